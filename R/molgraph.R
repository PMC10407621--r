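# Molecular graph layer: SMILES/SDF parsing, hydrogen filling, heavy-atom
# graphs, edge-adjacency matrices and topological distances.
#
# The parser covers the organic subset needed for small micropollutants:
# C/N/O/S/P plus halogens, aromatic ring atoms (c/n/o/s), branches, up to
# two-digit ring closures, bond symbols -/=/#/: and directional bonds
# (/ and \, read as single bonds; cis/trans geometry is not modeled).

# standard valences used for implicit-hydrogen filling
.ro_valence <- c(
  H = 1, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecule
#'
#' Builds an explicit molecular graph (atoms + bonds) from a SMILES string,
#' filling implicit hydrogens from standard valences (C4, N3, O2, S2, P3,
#' halogens 1). Aromatic bonds are stored with order 1.5; for descriptor
#' purposes all bond orders are treated as single graph edges.
#'
#' @param smiles SMILES string. Supported: element symbols C, N, O, S, P, F,
#'   Cl, Br, I (and aromatic c, n, o, s), branches `()`, ring closures
#'   (digits and `%nn`), bond symbols `-`, `=`, `#`, `:`, `/`, `\`, and
#'   simple bracket atoms such as `[CH4]` or `[nH]`.
#' @param name,abbrev optional compound name and abbreviation carried in the
#'   returned object.
#' @return an object of class `ro_molecule`: a list with `atoms` (data frame
#'   with columns `element`, `aromatic`, `x`, `y`, `z`) and `bonds` (data
#'   frame with columns `i`, `j`, `order`).
#' @examples
#' m <- parse_smiles("CC(C)(C)O")  # tert-butyl alcohol
#' sum(m$atoms$element != "H")     # 5 heavy atoms
#' @export
parse_smiles <- function(smiles, name = NA_character_, abbrev = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  element <- character(0)
  aromatic <- logical(0)
  explicit_h <- integer(0)  # NA = fill from valence
  bonds <- list()

  prev <- NA_integer_          # atom awaiting the next bond
  stack <- integer(0)          # branch stack
  ring <- list()               # ring-closure bookkeeping: label -> c(atom, order)
  pending_order <- NA_real_    # bond symbol seen before next atom/closure

  add_atom <- function(el, arom, hcount) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    explicit_h[length(explicit_h) + 1L] <<- hcount
    length(element)
  }
  add_bond <- function(a, b, order) {
    if (a == b) stop("SMILES parse error: self-bond at atom ", a)
    bonds[[length(bonds) + 1L]] <<- c(a, b, order)
  }
  connect <- function(idx) {
    force(idx)  # idx's promise appends the atom; force before reading state
    if (!is.na(prev)) {
      ord <- pending_order
      if (is.na(ord)) {
        ord <- if (aromatic[prev] && aromatic[idx]) 1.5 else 1
      }
      add_bond(prev, idx, ord)
    }
    prev <<- idx
    pending_order <<- NA_real_
  }
  close_ring <- function(label) {
    if (is.na(prev)) stop("SMILES parse error: ring closure before any atom")
    if (!is.null(ring[[label]])) {
      opened <- ring[[label]]
      ord <- pending_order
      if (is.na(ord)) ord <- opened[2]
      if (is.na(ord)) {
        ord <- if (aromatic[opened[1]] && aromatic[prev]) 1.5 else 1
      }
      add_bond(opened[1], prev, ord)
      ring[[label]] <<- NULL
    } else {
      ring[label] <<- list(c(prev, pending_order))
    }
    pending_order <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      connect(add_atom(two, FALSE, NA_integer_)); i <- i + 2L
    } else if (ch %in% c("C", "N", "O", "S", "P", "F", "I")) {
      connect(add_atom(ch, FALSE, NA_integer_)); i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "s")) {
      connect(add_atom(toupper(ch), TRUE, NA_integer_)); i <- i + 1L
    } else if (ch == "[") {
      close_pos <- i + match("]", chars[(i + 1L):n])
      if (is.na(close_pos)) stop("SMILES parse error: unterminated '[' at position ", i)
      body <- paste(chars[(i + 1L):(close_pos - 1L)], collapse = "")
      m <- regmatches(body, regexec("^([0-9]*)([A-Z][a-z]?|[cnos])(H([0-9]*))?([+-][0-9]*)?$", body))[[1]]
      if (length(m) == 0) stop("SMILES parse error: unsupported bracket atom [", body, "]")
      el <- m[3]; arom <- el %in% c("c", "n", "o", "s")
      if (arom) el <- toupper(el)
      hc <- if (m[4] == "") 0L else if (m[5] == "") 1L else as.integer(m[5])
      if (m[6] != "" && m[6] != "+0" && m[6] != "-0") {
        stop("SMILES parse error: charged atoms are not supported ([", body, "])")
      }
      connect(add_atom(el, arom, hc)); i <- close_pos + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("SMILES parse error: branch start before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("SMILES parse error: unmatched ')' at position ", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_order <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending_order <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending_order <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending_order <- 1.5; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("SMILES parse error: truncated % ring label")
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == ".") {
      stop("disconnected multi-fragment SMILES are rejected: ", smiles)
    } else {
      stop("SMILES parse error: unsupported token '", ch, "' at position ", i)
    }
  }
  if (length(ring) > 0) stop("SMILES parse error: unclosed ring bond(s): ",
                             paste(names(ring), collapse = ", "))
  if (length(stack) > 0) stop("SMILES parse error: unclosed branch")
  if (length(element) == 0) stop("SMILES parse error: no atoms in '", smiles, "'")

  atoms <- data.frame(element = element, aromatic = aromatic,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      stringsAsFactors = FALSE)
  bonds <- if (length(bonds)) {
    do.call(rbind.data.frame, lapply(bonds, function(b) {
      data.frame(i = b[1], j = b[2], order = b[3])
    }))
  } else data.frame(i = integer(0), j = integer(0), order = numeric(0))

  mol <- .ro_fill_hydrogens(atoms, bonds, explicit_h)
  mol$name <- name
  mol$abbrev <- abbrev
  mol$smiles <- smiles
  class(mol) <- "ro_molecule"
  .ro_check_connected(mol)
  mol
}

# add implicit hydrogens from standard valences; explicit_h overrides (NA = fill)
.ro_fill_hydrogens <- function(atoms, bonds, explicit_h) {
  n_heavy <- nrow(atoms)
  used <- numeric(n_heavy)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      used[bonds$i[b]] <- used[bonds$i[b]] + bonds$order[b]
      used[bonds$j[b]] <- used[bonds$j[b]] + bonds$order[b]
    }
  }
  for (a in seq_len(n_heavy)) {
    el <- atoms$element[a]
    if (!el %in% names(.ro_valence)) {
      stop("element '", el, "' is outside the supported valence table")
    }
    nh <- explicit_h[a]
    if (is.na(nh)) nh <- max(0L, .ro_valence[[el]] - as.integer(ceiling(used[a])))
    if (nh > 0) {
      for (k in seq_len(nh)) {
        atoms <- rbind(atoms, data.frame(element = "H", aromatic = FALSE,
                                         x = NA_real_, y = NA_real_, z = NA_real_))
        bonds <- rbind(bonds, data.frame(i = a, j = nrow(atoms), order = 1))
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

.ro_check_connected <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1L) return(invisible(TRUE))
  adj <- .ro_adjacency_list(mol$bonds, n)
  seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen)) stop("disconnected multi-fragment input rejected: ",
                       mol$smiles %||% "<structure>")
  invisible(TRUE)
}

.ro_adjacency_list <- function(bonds, n) {
  adj <- rep(list(integer(0)), n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  adj
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Parse a molecular structure from SMILES or an SDF record
#'
#' Dispatches on content: text containing a V2000/V3000 counts line is parsed
#' as an SDF/MOL record (3D coordinates retained); anything else is treated
#' as SMILES.
#'
#' @param source a SMILES string or the text of a single MOL/SDF record
#'   (character scalar or vector of lines).
#' @inheritParams parse_smiles
#' @return an `ro_molecule`.
#' @export
parse_structure <- function(source, name = NA_character_, abbrev = NA_character_) {
  txt <- paste(source, collapse = "\n")
  if (grepl("V2000", txt, fixed = TRUE)) {
    return(.ro_parse_sdf_v2000(strsplit(txt, "\n")[[1]], name, abbrev))
  }
  if (grepl("V3000", txt, fixed = TRUE)) {
    stop("V3000 SDF records are not supported; supply V2000 or SMILES")
  }
  parse_smiles(txt, name = name, abbrev = abbrev)
}

# minimal V2000 molfile reader: counts line, atom block (x y z element),
# bond block (i j order); explicit hydrogens expected, otherwise filled.
.ro_parse_sdf_v2000 <- function(lines, name, abbrev) {
  counts_at <- grep("V2000", lines, fixed = TRUE)[1]
  if (is.na(counts_at)) stop("SDF parse error: no V2000 counts line")
  cl <- lines[counts_at]
  n_at <- as.integer(substr(cl, 1, 3)); n_bd <- as.integer(substr(cl, 4, 6))
  if (is.na(n_at) || n_at < 1) stop("SDF parse error: bad counts line '", cl, "'")
  at_lines <- lines[(counts_at + 1):(counts_at + n_at)]
  atoms <- do.call(rbind.data.frame, lapply(at_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 4) stop("SDF parse error: bad atom line '", l, "'")
    data.frame(element = f[4], aromatic = FALSE,
               x = as.numeric(f[1]), y = as.numeric(f[2]), z = as.numeric(f[3]))
  }))
  bonds <- if (n_bd > 0) {
    bd_lines <- lines[(counts_at + n_at + 1):(counts_at + n_at + n_bd)]
    do.call(rbind.data.frame, lapply(bd_lines, function(l) {
      i <- as.integer(substr(l, 1, 3)); j <- as.integer(substr(l, 4, 6))
      o <- as.integer(substr(l, 7, 9))
      if (any(is.na(c(i, j, o))) || i == j || i > n_at || j > n_at) {
        stop("SDF parse error: bad bond line '", l, "'")
      }
      data.frame(i = i, j = j, order = if (o == 4) 1.5 else as.numeric(o))
    }))
  } else data.frame(i = integer(0), j = integer(0), order = numeric(0))
  has_h <- any(atoms$element == "H")
  mol <- if (has_h) list(atoms = atoms, bonds = bonds) else
    .ro_fill_hydrogens(atoms, bonds, rep(NA_integer_, n_at))
  mol$name <- name; mol$abbrev <- abbrev; mol$smiles <- NA_character_
  class(mol) <- "ro_molecule"
  .ro_check_connected(mol)
  mol
}

#' @export
print.ro_molecule <- function(x, ...) {
  nh <- sum(x$atoms$element == "H")
  cat("<ro_molecule>", x$name %||% "", "\n",
      " atoms:", nrow(x$atoms), "(", nrow(x$atoms) - nh, "heavy +", nh, "H )",
      " bonds:", nrow(x$bonds), "\n")
  invisible(x)
}

#' Hydrogen-depleted molecular graph
#'
#' Restricts a molecule to its non-hydrogen atoms. Bond orders are carried
#' along as edge attributes but are not used in adjacency structure: a double
#' bond is one graph edge.
#'
#' @param mol an `ro_molecule`.
#' @return an object of class `ro_graph` with `elements`, `aromatic`, and a
#'   `bonds` data frame (`i`, `j`, `order`) re-indexed over heavy atoms.
#' @export
heavy_atom_graph <- function(mol) {
  stopifnot(inherits(mol, "ro_molecule"))
  heavy <- which(mol$atoms$element != "H")
  map <- match(seq_len(nrow(mol$atoms)), heavy)
  keep <- !is.na(map[mol$bonds$i]) & !is.na(map[mol$bonds$j])
  bonds <- mol$bonds[keep, , drop = FALSE]
  if (length(heavy) < 2L || nrow(bonds) == 0L) {
    stop("molecule has no heavy-atom bonds; edge-adjacency descriptors undefined")
  }
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  structure(list(elements = mol$atoms$element[heavy],
                 aromatic = mol$atoms$aromatic[heavy],
                 bonds = bonds),
            class = "ro_graph")
}

#' Edge-adjacency matrix of a heavy-atom graph
#'
#' The edge-adjacency matrix `B` is indexed by heavy-atom bonds:
#' `B[e, f] = 1` when distinct bonds e and f share an atom (the line-graph
#' adjacency). With `weighting = "dipole"` the diagonal carries per-bond
#' dipole-moment weights looked up from the element pair and bond order;
#' with `weighting = "unweighted"` the diagonal is zero.
#'
#' @param graph an `ro_graph` from [heavy_atom_graph()].
#' @param weighting `"unweighted"` or `"dipole"`.
#' @param tables element tables from [ro_element_tables()] (used for dipole
#'   weights only).
#' @return an `ro_edge_adjacency`: list with `matrix`, `bonds`, `weighting`.
#' @export
edge_adjacency <- function(graph, weighting = c("unweighted", "dipole"),
                           tables = ro_element_tables()) {
  stopifnot(inherits(graph, "ro_graph"))
  weighting <- match.arg(weighting)
  bd <- graph$bonds
  m <- nrow(bd)
  B <- matrix(0, m, m)
  ends <- cbind(bd$i, bd$j)
  for (e in seq_len(m)) {
    shared <- (ends[, 1] %in% ends[e, ]) | (ends[, 2] %in% ends[e, ])
    B[e, shared] <- 1
  }
  diag(B) <- 0
  if (weighting == "dipole") {
    diag(B) <- vapply(seq_len(m), function(e) {
      .ro_dipole_weight(graph$elements[bd$i[e]], graph$elements[bd$j[e]],
                        bd$order[e], tables)
    }, numeric(1))
  }
  structure(list(matrix = B, bonds = bd, weighting = weighting),
            class = "ro_edge_adjacency")
}

.ro_dipole_weight <- function(el1, el2, order, tables) {
  pair <- paste(sort(c(el1, el2)), collapse = "-")
  okey <- if (order == 1.5) "ar" else as.character(as.integer(order))
  key <- paste0(pair, ":", okey)
  w <- tables$bond_dipole[[key]]
  if (is.null(w)) {
    stop("bond type ", key, " missing from the dipole-weight table; ",
         "extend the table (see ro_element_tables)")
  }
  w
}

#' Topological distance matrix
#'
#' Shortest-path bond counts between atoms (breadth-first search; bond
#' orders ignored).
#'
#' @param mol an `ro_molecule`.
#' @param include_h include hydrogen atoms (default `TRUE`; the GETAWAY
#'   descriptors use the hydrogen-included graph).
#' @return symmetric integer matrix with zero diagonal.
#' @export
topological_distance_matrix <- function(mol, include_h = TRUE) {
  stopifnot(inherits(mol, "ro_molecule"))
  keep <- if (include_h) seq_len(nrow(mol$atoms)) else which(mol$atoms$element != "H")
  map <- match(seq_len(nrow(mol$atoms)), keep)
  bonds <- mol$bonds[!is.na(map[mol$bonds$i]) & !is.na(map[mol$bonds$j]), , drop = FALSE]
  n <- length(keep)
  adj <- .ro_adjacency_list(data.frame(i = map[bonds$i], j = map[bonds$j]), n)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
    }
    D[s, ] <- dist
  }
  if (anyNA(D)) stop("molecule graph is not connected")
  D
}

# typical bond lengths (Angstrom) for the distance-geometry embedding
.ro_bond_length <- function(el1, el2, order) {
  pair <- paste(sort(c(el1, el2)), collapse = "-")
  len <- list(
    "C-C" = c(`1` = 1.54, `1.5` = 1.39, `2` = 1.34, `3` = 1.20),
    "C-H" = c(`1` = 1.09), "H-H" = c(`1` = 0.74),
    "C-O" = c(`1` = 1.43, `2` = 1.22, `1.5` = 1.36),
    "C-N" = c(`1` = 1.47, `2` = 1.28, `3` = 1.16, `1.5` = 1.34),
    "C-Cl" = c(`1` = 1.77), "Br-C" = c(`1` = 1.94), "C-I" = c(`1` = 2.14),
    "C-F" = c(`1` = 1.35), "C-S" = c(`1` = 1.82, `1.5` = 1.71),
    "H-O" = c(`1` = 0.96), "H-N" = c(`1` = 1.01), "H-S" = c(`1` = 1.34)
  )
  v <- len[[pair]]
  if (!is.null(v) && as.character(order) %in% names(v)) return(v[[as.character(order)]])
  1.5
}

#' Deterministic 3D coordinate embedding
#'
#' Generates approximate 3D coordinates from the molecular graph alone:
#' interatomic distance estimates (bond lengths for neighbors, law-of-cosines
#' valence angles for 1-3 pairs, damped shortest paths beyond) are embedded
#' into three dimensions by classical multidimensional scaling. Fully
#' deterministic. Geometry-dependent descriptors (R2e) computed from embedded
#' coordinates deviate from quantum-optimized geometries; a warning is issued
#' once per call.
#'
#' @param mol an `ro_molecule`.
#' @param quiet suppress the geometry warning.
#' @return the molecule with `x`, `y`, `z` filled for every atom.
#' @export
embed_coordinates <- function(mol, quiet = FALSE) {
  stopifnot(inherits(mol, "ro_molecule"))
  n <- nrow(mol$atoms)
  if (n == 1L) { mol$atoms[, c("x", "y", "z")] <- 0; return(mol) }
  Dtop <- topological_distance_matrix(mol, include_h = TRUE)
  blen <- matrix(0, n, n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    l <- .ro_bond_length(mol$atoms$element[i], mol$atoms$element[j], mol$bonds$order[b])
    blen[i, j] <- l; blen[j, i] <- l
  }
  # per-atom valence angle guess from maximum incident bond order
  maxord <- vapply(seq_len(n), function(a) {
    inc <- mol$bonds$order[mol$bonds$i == a | mol$bonds$j == a]
    if (length(inc)) max(inc) else 1
  }, numeric(1))
  angle <- ifelse(maxord >= 3, pi,
           ifelse(maxord >= 1.5, 120 * pi / 180, acos(-1 / 3)))
  D <- matrix(0, n, n)
  adj <- .ro_adjacency_list(mol$bonds, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    d <- Dtop[i, j]
    if (d == 1L) {
      D[i, j] <- blen[i, j]
    } else if (d == 2L) {
      mid <- intersect(adj[[i]], adj[[j]])[1]
      a <- blen[i, mid]; b <- blen[mid, j]
      D[i, j] <- sqrt(a^2 + b^2 - 2 * a * b * cos(angle[mid]))
    } else {
      # damped through-bond estimate for remote pairs
      D[i, j] <- 1.45 * d * 0.85
    }
    D[j, i] <- D[i, j]
  }
  xyz <- stats::cmdscale(stats::as.dist(D), k = min(3L, n - 1L))
  if (ncol(xyz) < 3L) xyz <- cbind(xyz, matrix(0, n, 3L - ncol(xyz)))
  xyz <- .ro_smacof(xyz, D)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  if (!quiet) {
    warning("coordinates from graph embedding: geometry-dependent descriptors ",
            "(R2e) will deviate from quantum-optimized geometries", call. = FALSE)
  }
  mol
}

# stress-majorization (SMACOF) refinement of a 3D embedding toward the
# target distance matrix; classical MDS truncated to 3D can place atoms of
# symmetric molecules at coincident points, which this pulls apart. A fixed
# deterministic perturbation breaks exact coincidences.
.ro_smacof <- function(X, D, iters = 80L) {
  n <- nrow(X)
  if (n < 3L) return(X)
  # deterministic symmetry-breaking nudge (no RNG: reproducible everywhere)
  nudge <- outer(seq_len(n), 1:3, function(i, k) sin(i * 7.13 + k * 2.41)) * 1e-3
  X <- X + nudge
  for (it in seq_len(iters)) {
    d <- as.matrix(stats::dist(X))
    ratio <- ifelse(d > 1e-9, D / d, 0)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
  }
  X
}
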