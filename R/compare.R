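# Collation of two model iterations: chain pairing and global sequence
# alignment so both versions can share one chain-view.

#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch with linear gap penalty and a deterministic traceback
#' (prefer diagonal, then up = gap in `seq_b`, then left). `"X"` (unknown
#' residue) scores 0 against anything.
#'
#' @param seq_a,seq_b non-empty one-letter sequences (character scalars).
#' @param match,mismatch,gap scoring scheme (defaults +1 / -1 / -2).
#' @return list with `a_idx`, `b_idx` (integer vectors over alignment
#'   columns, `NA` at gaps), `score`, and the aligned strings `a_aln`,
#'   `b_aln` (gaps as `-`).
#' @export
align_sequences <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  stopifnot(length(a) > 0, length(b) > 0)
  n <- length(a); m <- length(b)
  sub <- function(x, y) {
    if (x == "X" || y == "X") 0 else if (x == y) match else mismatch
  }
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  # traceback codes: 1 diagonal, 2 up (consume a), 3 left (consume b)
  Tb <- matrix(0L, n + 1, m + 1)
  Tb[, 1] <- 2L; Tb[1, ] <- 3L; Tb[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + sub(a[i], b[j])
      u <- S[i, j + 1] + gap
      l <- S[i + 1, j] + gap
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      Tb[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  ai <- integer(0); bi <- integer(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- Tb[i, j]
    if (mv == 1L) {
      ai <- c(i - 1L, ai); bi <- c(j - 1L, bi); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ai <- c(i - 1L, ai); bi <- c(NA_integer_, bi); i <- i - 1L
    } else {
      ai <- c(NA_integer_, ai); bi <- c(j - 1L, bi); j <- j - 1L
    }
  }
  list(a_idx = ai, b_idx = bi, score = S[n + 1, m + 1],
       a_aln = paste(ifelse(is.na(ai), "-", a[ai]), collapse = ""),
       b_aln = paste(ifelse(is.na(bi), "-", b[bi]), collapse = ""))
}

#' Pair chains between two model iterations
#'
#' Chains with identical ids are paired first; the leftovers are paired
#' greedily by best alignment score; chains present in only one version are
#' reported unpaired. Pairing is stable under permutation of chain order
#' (candidates are scanned in lexicographic chain-id order and ties broken
#' the same way).
#'
#' @param latest,previous `StructureModel`s (`previous` may be `NULL`).
#' @param ... scoring parameters passed to [align_sequences()].
#' @return list of `AlignedPair` objects: `chain_id_latest`,
#'   `chain_id_previous` (either may be `NA` for unpaired chains), and
#'   `alignment` (as returned by [align_sequences()]; `NULL` when unpaired).
#' @export
pair_chains <- function(latest, previous = NULL, ...) {
  lat_ids <- vapply(latest$chains, `[[`, "", "chain_id")
  if (is.null(previous)) {
    return(lapply(lat_ids, function(id) {
      structure(list(chain_id_latest = id, chain_id_previous = NA_character_,
                     alignment = NULL), class = "AlignedPair")
    }))
  }
  prev_ids <- vapply(previous$chains, `[[`, "", "chain_id")
  seq_of <- function(model, id) {
    chain_sequence(model$chains[[match(id, vapply(model$chains, `[[`, "", "chain_id"))]])
  }
  pairs <- list()
  used_prev <- character(0)
  # 1) identity pairing
  for (id in sort(lat_ids)) {
    if (id %in% prev_ids) {
      pairs[[length(pairs) + 1L]] <- structure(
        list(chain_id_latest = id, chain_id_previous = id,
             alignment = align_sequences(seq_of(latest, id), seq_of(previous, id), ...)),
        class = "AlignedPair")
      used_prev <- c(used_prev, id)
    }
  }
  left_lat <- sort(setdiff(lat_ids, prev_ids))
  left_prev <- sort(setdiff(prev_ids, lat_ids))
  # 2) greedy score pairing of leftovers
  while (length(left_lat) && length(left_prev)) {
    sc <- outer(left_lat, left_prev, Vectorize(function(li, pi) {
      align_sequences(seq_of(latest, li), seq_of(previous, pi), ...)$score
    }))
    best <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    li <- left_lat[best[1]]; pi <- left_prev[best[2]]
    pairs[[length(pairs) + 1L]] <- structure(
      list(chain_id_latest = li, chain_id_previous = pi,
           alignment = align_sequences(seq_of(latest, li), seq_of(previous, pi), ...)),
      class = "AlignedPair")
    left_lat <- setdiff(left_lat, li)
    left_prev <- setdiff(left_prev, pi)
  }
  for (id in left_lat)
    pairs[[length(pairs) + 1L]] <- structure(
      list(chain_id_latest = id, chain_id_previous = NA_character_,
           alignment = NULL), class = "AlignedPair")
  for (id in left_prev)
    pairs[[length(pairs) + 1L]] <- structure(
      list(chain_id_latest = NA_character_, chain_id_previous = id,
           alignment = NULL), class = "AlignedPair")
  pairs
}

#' Collate per-residue metrics of two iterations along an alignment
#'
#' Produces one output row per alignment column. The side that carries a gap
#' at a column is marked missing (rendered as a black rim spot in the
#' chain-view).
#'
#' @param pair an `AlignedPair`.
#' @param metrics_latest,metrics_previous per-chain metrics data frames as
#'   produced by [chain_metrics()] (rows in residue order);
#'   `metrics_previous` may be `NULL` for single-version input.
#' @return data frame with the latest metrics columns, the previous metrics
#'   columns prefixed `prev_`, and logical `missing_latest`,
#'   `missing_previous`.
#' @export
collate_metrics <- function(pair, metrics_latest, metrics_previous = NULL) {
  if (is.null(pair$alignment) || is.null(metrics_previous)) {
    out <- metrics_latest
    out$missing_latest <- FALSE
    out$missing_previous <- NA
    prev_cols <- paste0("prev_", setdiff(names(metrics_latest),
                                         c("chain", "seq_num", "icode", "name")))
    for (cn in prev_cols) out[[cn]] <- NA
    return(out)
  }
  aln <- pair$alignment
  ncol_aln <- length(aln$a_idx)
  take <- function(df, idx) {
    out <- df[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    out[is.na(idx), ] <- NA
    rownames(out) <- NULL
    out
  }
  lat <- take(metrics_latest, aln$a_idx)
  prv <- take(metrics_previous, aln$b_idx)
  names(prv) <- paste0("prev_", names(prv))
  out <- cbind(lat, prv)
  out$missing_latest <- is.na(aln$a_idx)
  out$missing_previous <- is.na(aln$b_idx)
  stopifnot(nrow(out) == ncol_aln)
  out
}
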