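# Shared helpers and independent oracles used across the test files.

# Build a bare Residue object without going through a file.
make_residue <- function(name, atom_names, b = NULL, xyz = NULL,
                         elements = NULL, seq_num = 1) {
  n <- length(atom_names)
  if (is.null(b)) b <- rep(20, n)
  if (is.null(xyz)) xyz <- matrix(seq_len(3 * n), ncol = 3)
  if (is.null(elements)) elements <- chainview:::element_from_name(atom_names)
  res <- list(seq_num = seq_num, insertion_code = "", name = name,
              atoms = data.frame(name = atom_names, element = elements,
                                 proton = chainview:::proton_number(elements),
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 b = b, occupancy = 1, altloc = "",
                                 stringsAsFactors = FALSE))
  res$is_amino_acid <- is_amino_acid(res)
  class(res) <- "Residue"
  res
}

# Exhaustive global-alignment oracle: enumerates every alignment of a and b
# recursively and returns the maximum score. Only viable for short sequences.
brute_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sub <- function(x, y) if (x == "X" || y == "X") 0 else if (x == y) match else mismatch
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, sub(av[i], bv[j]) + rec(i + 1, j + 1))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Brute-force flat index oracle: enumerate the ordered coordinate lattice
# row-major (last dimension fastest) and look the coordinate up by position.
brute_grid_index <- function(node_ids, sizes) {
  lattice <- as.matrix(expand.grid(rev(lapply(sizes, function(s) 0:(s - 1)))))
  lattice <- lattice[, rev(seq_along(sizes)), drop = FALSE]
  hit <- which(apply(lattice, 1, function(r) all(r == node_ids)))
  hit - 1L
}

# A tiny random raw contour-grid library for round-trip tests.
random_raw_library <- function(seed, n_types = 2) {
  set.seed(seed)
  out <- list()
  for (t in seq_len(n_types)) {
    nd <- sample(1:3, 1)
    sizes <- sample(2:6, nd, replace = TRUE)
    spacing <- 360 / sizes
    lattice <- as.matrix(expand.grid(lapply(seq_len(nd), function(d)
      -180 + (0:(sizes[d] - 1)) * spacing[d])))
    colnames(lattice) <- NULL
    listed <- runif(nrow(lattice)) < 0.7
    out[[paste0("TY", t)]] <- list(
      coords = lattice[listed, , drop = FALSE],
      values = round(runif(sum(listed), 0, 4), 3),
      axis_origins = rep(-180, nd), axis_spacings = spacing,
      axis_sizes = sizes)
  }
  out
}

# Reference data is deterministic and cached; share one bundle.
test_refdata <- default_reference_data()
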