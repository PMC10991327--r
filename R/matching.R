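# Cross-condition wave matching by the MSE of reconstructed correlation
# matrices.

#' Mean squared error between two correlation matrices
#'
#' Mean of the squared elementwise differences over the strict upper
#' triangle (the diagonal is excluded; for symmetric matrices the full-matrix
#' and upper-triangle means differ only by a constant factor and never change
#' a ranking). Entries undefined in either matrix are skipped.
#'
#' @param fc_a,fc_b Square matrices on the same node set.
#' @return A value >= 0; 0 iff the (defined) off-diagonal entries coincide.
#' @export
correlation_mse <- function(fc_a, fc_b) {
  if (!identical(dim(fc_a), dim(fc_b))) {
    stop("matrices are on different node sets")
  }
  ut <- upper.tri(fc_a)
  d <- (unclass(fc_a)[ut] - unclass(fc_b)[ut])^2
  mean(d, na.rm = TRUE)
}

#' Match waves across two decompositions
#'
#' Computes the full matrix of MSEs between the wave correlation matrices of
#' a query and a reference decomposition and assigns each query wave to the
#' reference wave with the lowest MSE (per-row argmin; ties broken toward
#' the lower reference index). Because each wave's correlation matrix
#' depends only on phase differences, the match is invariant to per-wave
#' global phase rotations. The argmin rule can assign two query waves to
#' the same reference wave; such collisions are reported, and
#' `one_to_one = TRUE` switches to a minimum-total-MSE one-to-one assignment
#' (exhaustive for up to 8 waves, greedy beyond).
#'
#' @param query,reference `wave_decomposition` objects on the same grid.
#' @param one_to_one Force an injective assignment; default `FALSE`.
#' @return An object of class `wave_match`: a list with `mse` (matrix,
#'   query x reference), `assignment` (tibble: `query`, `reference`, `mse`),
#'   `injective`.
#' @export
match_waves <- function(query, reference, one_to_one = FALSE) {
  stopifnot(inherits(query, "wave_decomposition"),
            inherits(reference, "wave_decomposition"))
  if (query$n_pixels != reference$n_pixels ||
      !identical(query$pixel_index, reference$pixel_index)) {
    stop("decompositions are on different pixel grids")
  }
  if (query$n_components == 0 || reference$n_components == 0) {
    stop("empty decomposition")
  }
  q_fc <- lapply(seq_len(query$n_components), function(k) wave_fc(query, k))
  r_fc <- lapply(seq_len(reference$n_components), function(k) wave_fc(reference, k))
  mse <- outer(seq_along(q_fc), seq_along(r_fc),
               Vectorize(function(i, j) correlation_mse(q_fc[[i]], r_fc[[j]])))
  if (one_to_one) {
    ref_of <- one_to_one_assignment(mse)
  } else {
    ref_of <- apply(mse, 1, which.min)  # which.min breaks ties to lower index
  }
  assignment <- tibble::tibble(
    query = seq_len(nrow(mse)),
    reference = ref_of,
    mse = mse[cbind(seq_len(nrow(mse)), ref_of)]
  )
  structure(
    list(mse = mse, assignment = assignment,
         injective = !anyDuplicated(stats::na.omit(ref_of))),
    class = "wave_match"
  )
}

#' @export
print.wave_match <- function(x, ...) {
  cat(sprintf("<wave_match> %d query x %d reference waves%s\n",
              nrow(x$mse), ncol(x$mse),
              if (x$injective) "" else " (non-injective argmin)"))
  print(x$assignment)
  invisible(x)
}

# Minimum-total-MSE one-to-one assignment of rows to columns. Exact by
# enumeration for small problems, greedy otherwise. Rows beyond the column
# count stay unassigned (NA).
one_to_one_assignment <- function(mse) {
  nq <- nrow(mse); nr <- ncol(mse)
  k <- min(nq, nr)
  if (nq <= 8 && nr <= 8) {
    perms <- all_permutations(nr, k)
    rows_used <- seq_len(k)
    best <- NULL; best_cost <- Inf
    for (i in seq_len(nrow(perms))) {
      cost <- sum(mse[cbind(rows_used, perms[i, ])])
      if (cost < best_cost) { best_cost <- cost; best <- perms[i, ] }
    }
    out <- rep(NA_integer_, nq)
    out[rows_used] <- best
    out
  } else {
    out <- rep(NA_integer_, nq)
    m <- mse
    for (step in seq_len(k)) {
      idx <- arrayInd(which.min(m), dim(m))
      out[idx[1]] <- idx[2]
      m[idx[1], ] <- Inf
      m[, idx[2]] <- Inf
    }
    out
  }
}

# All ordered selections of k items from 1..n (k-permutations).
all_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (col in seq_len(k - 1)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(out[i, ], length(rest), col, byrow = TRUE), rest)
    }))
  }
  unname(out)
}
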