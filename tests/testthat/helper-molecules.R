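# Shared fixtures: golden-value molecules, random tree generators, and a
# chloroform SDF with near-experimental geometry.

golden_smiles <- list(
  ctet = "ClC(Cl)(Cl)Cl",
  tca1112 = "ClCC(Cl)(Cl)Cl",
  tca112 = "ClCC(Cl)Cl",
  bromoform = "BrC(Br)Br",
  tba = "CC(C)(C)O",
  ipa = "CC(C)O",
  tdce = "Cl/C=C/Cl",
  benzene = "c1ccccc1",
  chlorobenzene = "Clc1ccccc1",
  naphthalene = "c1ccc2ccccc2c1"
)

# random alkane tree with max degree 4, emitted as nested SMILES
random_alkane_smiles <- function(n_carbons, seed) {
  set.seed(seed)
  parent <- rep(NA_integer_, n_carbons)
  deg <- integer(n_carbons)
  for (a in seq_len(n_carbons)[-1]) {
    open <- which(deg[seq_len(a - 1L)] < 4L)
    p <- if (length(open) == 1L) open else sample(open, 1L)
    parent[a] <- p
    deg[p] <- deg[p] + 1L
    deg[a] <- deg[a] + 1L
  }
  children <- lapply(seq_len(n_carbons), function(a) which(parent == a))
  emit <- function(a) {
    kids <- children[[a]]
    if (length(kids) == 0L) return("C")
    inner <- vapply(kids, emit, character(1))
    if (length(inner) > 1L) {
      paste0("C", paste0("(", inner[-length(inner)], ")", collapse = ""),
             inner[length(inner)])
    } else paste0("C", inner)
  }
  emit(1L)
}

# V2000 record for chloroform at near-experimental geometry
# (C-H 1.100 A, C-Cl 1.758 A, Cl-C-Cl 111.3 deg, C3v symmetry)
chloroform_sdf <- function() {
  ang <- 111.3 * pi / 180
  f <- function(t) {
    d1 <- c(sin(t), 0, cos(t))
    d2 <- c(sin(t) * cos(2 * pi / 3), sin(t) * sin(2 * pi / 3), cos(t))
    sum(d1 * d2) - cos(ang)
  }
  t <- uniroot(f, c(pi / 2, pi))$root
  dirs <- sapply(0:2, function(k) {
    c(sin(t) * cos(2 * pi * k / 3), sin(t) * sin(2 * pi * k / 3), cos(t))
  })
  coords <- rbind(c(0, 0, 0), c(0, 0, 1.100), t(dirs) * 1.758)
  elem <- c("C", "H", "Cl", "Cl", "Cl")
  atom_block <- paste(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[, 1], coords[, 2], coords[, 3], elem),
                      collapse = "\n")
  bond_block <- paste(sprintf("%3d%3d%3d  0  0  0  0", 1L, 2:5, 1L), collapse = "\n")
  paste("chloroform", "  synthetic geometry", "",
        "  5  4  0  0  0  0  0  0  0  0999 V2000",
        atom_block, bond_block, "M  END", sep = "\n")
}

# independent loop-based line-graph adjacency (oracle; no package code)
oracle_line_adjacency <- function(bonds, diagw = NULL) {
  m <- nrow(bonds)
  B <- matrix(0, m, m)
  for (e in seq_len(m)) for (f in seq_len(m)) {
    if (e != f && length(intersect(c(bonds$i[e], bonds$j[e]),
                                   c(bonds$i[f], bonds$j[f]))) > 0) B[e, f] <- 1
  }
  if (!is.null(diagw)) diag(B) <- diagw
  B
}

# fixture descriptor table is expensive (embedding); compute once per run
fixture_descriptors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- load_fixture()
      mols <- lapply(seq_len(nrow(rec)), function(i) {
        parse_smiles(rec$smiles[i], name = rec$name[i], abbrev = rec$abbrev[i])
      })
      cache <<- suppressWarnings(descriptor_table(mols, embed_missing = TRUE))
    }
    cache
  }
})
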