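# The four selected descriptor families: information-content indices (SIC),
# edge-adjacency spectral moments (ESpm) and eigenvalues (EEig), and the
# GETAWAY R autocorrelation weighted by Sanderson electronegativity (R2e).

#' Element and bond parameter tables
#'
#' Loads the Sanderson electronegativity table (returned carbon-normalized,
#' so `sanderson_en["C"] == 1`) and the bond dipole-moment weight table used
#' by the dipole-weighted edge-adjacency descriptors. Carbon-carbon bonds of
#' every order (single, double, triple, aromatic) carry weight 0.
#'
#' @param path optional path to a user-edited YAML file with the same layout
#'   as the packaged `element_tables.yaml`.
#' @return list with `sanderson_en` (named numeric, carbon = 1) and
#'   `bond_dipole` (named list keyed `"El1-El2:order"`).
#' @export
ro_element_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "element_tables.yaml", package = "roqsar")
  }
  tab <- yaml::read_yaml(path)
  en <- unlist(tab$sanderson_en)
  if (!"C" %in% names(en)) stop("element table must define carbon electronegativity")
  en <- en / en[["C"]]
  stopifnot(abs(en[["C"]] - 1) < 1e-12)
  list(sanderson_en = en, bond_dipole = tab$bond_dipole)
}

#' Structural information content index (SIC)
#'
#' Atoms (hydrogens included) are partitioned into equivalence classes:
#' order 0 groups atoms of the same element; each further order refines the
#' classes by the multiset of neighbor classes (bond orders ignored). The
#' Shannon information content of the order-`m` partition,
#' `IC_m = -sum_g (n_g/A) log2(n_g/A)`, is normalized by its maximum
#' `log2(A)` to give `SIC_m` in `[0, 1]`.
#'
#' @param mol an `ro_molecule`.
#' @param order neighborhood-symmetry order (default 1).
#' @return `SIC_order`, dimensionless in `[0, 1]`.
#' @examples
#' sic(parse_smiles("ClC(Cl)(Cl)Cl"))  # carbon tetrachloride: 0.311
#' @export
sic <- function(mol, order = 1L) {
  stopifnot(inherits(mol, "ro_molecule"), order >= 0L)
  A <- nrow(mol$atoms)
  if (A < 2L) stop("SIC is undefined for a single-atom molecule (log2(1) = 0)")
  cls <- .ro_symmetry_classes(mol, order)
  n_g <- table(cls)
  p <- as.numeric(n_g) / A
  ic <- -sum(p * log2(p))
  ic / log2(A)
}

# order-m neighborhood-symmetry classes over all atoms (H included)
.ro_symmetry_classes <- function(mol, order) {
  n <- nrow(mol$atoms)
  adj <- .ro_adjacency_list(mol$bonds, n)
  cls <- match(mol$atoms$element, unique(mol$atoms$element))
  m <- 0L
  while (m < order) {
    key <- vapply(seq_len(n), function(a) {
      paste(cls[a], paste(sort(cls[adj[[a]]]), collapse = ","), sep = "|")
    }, character(1))
    new_cls <- match(key, unique(key))
    if (identical(new_cls, match(cls, unique(cls)))) break  # partition stable
    cls <- new_cls
    m <- m + 1L
  }
  cls
}

#' Edge-adjacency spectral moment descriptor (ESpm)
#'
#' `ln(1 + trace(B^k))` where `B` is the unweighted edge-adjacency matrix of
#' the hydrogen-depleted graph; the trace counts closed walks of length `k`
#' over bonds. Two computation routes are provided (eigenvalue powers and
#' repeated matrix multiplication) and must agree.
#'
#' @param mol an `ro_molecule` with at least one heavy-atom bond.
#' @param k walk length (default 14).
#' @param method `"eigen"` (default) or `"power"`.
#' @return dimensionless value `>= 0`.
#' @examples
#' espm(parse_smiles("CC(C)(C)O"))  # tert-butyl alcohol: 15.381
#' @export
espm <- function(mol, k = 14L, method = c("eigen", "power")) {
  stopifnot(inherits(mol, "ro_molecule"))
  if (k < 1L) stop("spectral moment order k must be >= 1")
  method <- match.arg(method)
  B <- edge_adjacency(heavy_atom_graph(mol), "unweighted")$matrix
  tr <- if (method == "eigen") {
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    sum(ev^k)
  } else {
    P <- diag(nrow(B))
    for (s in seq_len(k)) P <- P %*% B
    sum(diag(P))
  }
  log(1 + tr)
}

#' Edge-adjacency eigenvalue descriptor (EEig)
#'
#' The `rank`-th largest eigenvalue (descending by value, not absolute
#' value) of the edge-adjacency matrix with per-bond weights on the
#' diagonal. The default dipole weighting places bond dipole moments on the
#' diagonal; carbon-carbon bonds weigh 0, so for pure hydrocarbons the
#' matrix reduces to the line-graph adjacency.
#'
#' @param mol an `ro_molecule`.
#' @param rank which eigenvalue (default 3).
#' @param weighting `"dipole"` (default) or `"unweighted"`.
#' @param tables element tables from [ro_element_tables()].
#' @return dimensionless value; molecules with fewer than `rank` heavy-atom
#'   bonds return 0 with a warning (documented fallback).
#' @examples
#' eeig(parse_smiles("c1ccccc1"))  # benzene: 1
#' @export
eeig <- function(mol, rank = 3L, weighting = c("dipole", "unweighted"),
                 tables = ro_element_tables()) {
  stopifnot(inherits(mol, "ro_molecule"), rank >= 1L)
  weighting <- match.arg(weighting)
  graph <- heavy_atom_graph(mol)
  if (nrow(graph$bonds) < rank) {
    warning("fewer than ", rank, " heavy-atom bonds; EEig", rank,
            " falls back to 0", call. = FALSE)
    return(0)
  }
  B <- edge_adjacency(graph, weighting, tables)$matrix
  ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[rank]
}

#' GETAWAY R autocorrelation of lag 2 (R2e)
#'
#' From centered atomic coordinates `M` (hydrogens included) the molecular
#' influence matrix is `H = M (M'M)^+ M'` (pseudo-inverse, so planar and
#' linear geometries are handled). R2e sums, over unordered atom pairs at
#' topological distance 2, `sqrt(h_ii h_jj) / r_ij * e_i * e_j` with `r_ij`
#' the Euclidean distance in Angstrom and `e` carbon-normalized Sanderson
#' electronegativities.
#'
#' @param mol an `ro_molecule` with 3D coordinates on every atom (from an
#'   SDF record or [embed_coordinates()]).
#' @param tables element tables from [ro_element_tables()].
#' @return dimensionless value `>= 0` (for positive weights).
#' @export
r2e <- function(mol, tables = ro_element_tables()) {
  stopifnot(inherits(mol, "ro_molecule"))
  M <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (anyNA(M)) {
    stop("molecule has atoms without 3D coordinates; supply an SDF with ",
         "coordinates or call embed_coordinates() first")
  }
  en <- tables$sanderson_en
  missing_el <- setdiff(unique(mol$atoms$element), names(en))
  if (length(missing_el)) {
    stop("element(s) absent from the electronegativity table: ",
         paste(missing_el, collapse = ", "))
  }
  e <- en[mol$atoms$element]
  Mc <- sweep(M, 2, colMeans(M))
  sv <- svd(Mc)
  pos <- sv$d > 1e-10
  h <- if (any(pos)) {
    U <- sv$u[, pos, drop = FALSE]
    rowSums(U * U)
  } else rep(0, nrow(Mc))
  D <- topological_distance_matrix(mol, include_h = TRUE)
  idx <- which(D == 2L & upper.tri(D), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  tot <- 0
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    rij <- sqrt(sum((M[i, ] - M[j, ])^2))
    tot <- tot + sqrt(h[i] * h[j]) / rij * e[[i]] * e[[j]]
  }
  tot
}

#' Compute a descriptor table for a set of molecules
#'
#' Evaluates the selected descriptors for each molecule and assembles the
#' rectangular compound-by-descriptor table (column order `SIC1, R2e,
#' EEig03d, ESpm14u`). Per-compound failures are collected and reported
#' together; a partial table is never returned silently.
#'
#' @param mols list of `ro_molecule` objects (or a character vector of
#'   SMILES, which is parsed).
#' @param which descriptor names, subset of
#'   `c("SIC1", "R2e", "EEig03d", "ESpm14u")`.
#' @param embed_missing if `TRUE`, molecules lacking coordinates are embedded
#'   with [embed_coordinates()] before computing R2e (one warning for the
#'   whole batch).
#' @param tables element tables from [ro_element_tables()].
#' @return data frame with a `compound` column followed by one column per
#'   descriptor; attribute `provenance` records geometry sources.
#' @export
descriptor_table <- function(mols, which = c("SIC1", "R2e", "EEig03d", "ESpm14u"),
                             embed_missing = FALSE,
                             tables = ro_element_tables()) {
  which <- match.arg(which, c("SIC1", "R2e", "EEig03d", "ESpm14u"),
                     several.ok = TRUE)
  if (is.character(mols)) mols <- lapply(mols, parse_smiles)
  if (length(mols) == 0L) {
    out <- data.frame(compound = character(0))
    for (w in which) out[[w]] <- numeric(0)
    return(out)
  }
  embedded <- FALSE
  rows <- vector("list", length(mols))
  errors <- character(0)
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    cname <- mol$name %||% mol$abbrev %||% mol$smiles %||% as.character(k)
    res <- tryCatch({
      if ("R2e" %in% which && anyNA(mol$atoms$x)) {
        if (!embed_missing) {
          stop("no 3D coordinates (use embed_missing = TRUE or supply SDF)")
        }
        mol <- embed_coordinates(mol, quiet = TRUE)
        embedded <- TRUE
      }
      vals <- c(
        SIC1 = if ("SIC1" %in% which) sic(mol, 1L) else NA_real_,
        R2e = if ("R2e" %in% which) r2e(mol, tables) else NA_real_,
        EEig03d = if ("EEig03d" %in% which) eeig(mol, 3L, "dipole", tables) else NA_real_,
        ESpm14u = if ("ESpm14u" %in% which) espm(mol, 14L) else NA_real_
      )
      c(list(compound = cname), as.list(vals[which]))
    }, error = function(e) {
      errors <<- c(errors, paste0(cname, ": ", conditionMessage(e)))
      NULL
    })
    rows[[k]] <- res
  }
  if (length(errors)) {
    stop("descriptor computation failed for ", length(errors), " compound(s):\n  ",
         paste(errors, collapse = "\n  "))
  }
  out <- do.call(rbind.data.frame, rows)
  rownames(out) <- NULL
  if (embedded) {
    warning("R2e computed from graph-embedded coordinates for at least one ",
            "compound; values deviate from quantum-optimized geometries",
            call. = FALSE)
  }
  attr(out, "provenance") <- list(
    geometry = if (embedded) "graph embedding (at least partly)" else "input coordinates or not required",
    tables = "ro_element_tables"
  )
  out
}

#' Write / read a descriptor table as CSV
#'
#' @param table data frame from [descriptor_table()].
#' @param path file path.
#' @return `read_descriptor_csv` returns the data frame.
#' @export
write_descriptor_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"compound" %in% names(out)) stop("descriptor CSV must have a 'compound' column")
  out
}
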