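#' Leave-out splits for dose-response matrices
#'
#' Train/test splitting protocols for posterior-predictive evaluation. The
#' base point (all doses zero) is never eligible for the test set; only
#' points with a non-zero dose are left out.
#'
#' * `split_dream()` expects the 6x6 screening layout (1 base cell, two
#'   5-point monotherapy slices, a 5x5 combination grid = 35 non-base
#'   points) and leaves out 7 of the 35 (20%): exactly one point from each
#'   monotherapy slice — so every monotherapy retains a held-out
#'   measurement — plus 5 of the 25 grid points, all chosen uniformly at
#'   random.
#' * `split_almanac()` expects the 15-point layout (two 3-point monotherapy
#'   slices plus a 3x3 grid) and leaves out 3 of the 15 points uniformly,
#'   with no per-slice constraint: the slices are too small to reserve
#'   points separately.
#' * `split_fraction()` leaves out a fraction of the non-base points of any
#'   dataset (monotherapy or combination) uniformly at random.
#'
#' Splits are deterministic given `seed`; the random choice is sampling
#' without replacement after a seeded shuffle of the row indices.
#'
#' @param data A [dose_response()] combination matrix (any dataset for
#'   `split_fraction()`).
#' @param seed Integer seed.
#' @param fraction Fraction of non-base points to hold out.
#' @return A `dr_split`: list with `train` and `test` ([dose_response()]
#'   objects), `strategy`, `seed` and `test_idx` (row indices into `data`,
#'   serialisable for exact reproduction).
#' @examples
#' sim <- simulate_dose_matrix("dream_6x6", seed = 1)
#' sp <- split_dream(sim$data, seed = 2)
#' nrow(sp$test) # 7
#' @export
split_dream <- function(data, seed = 1L) {
  stopifnot(inherits(data, "dose_response"))
  if (dr_setting(data) != "combo") {
    abort("split_dream() needs a combination matrix (6x6 layout).")
  }
  base <- which(data$dose1 == 0 & data$dose2 == 0)
  mono1 <- which(data$dose1 > 0 & data$dose2 == 0)
  mono2 <- which(data$dose1 == 0 & data$dose2 > 0)
  grid <- which(data$dose1 > 0 & data$dose2 > 0)
  if (length(base) != 1 || length(mono1) != 5 || length(mono2) != 5 ||
    length(grid) != 25) {
    abort(paste0(
      "expected the 6x6 layout (1 base + 5 + 5 monotherapy + 25 grid points); got ",
      length(base), " + ", length(mono1), " + ", length(mono2), " + ", length(grid), "."
    ))
  }
  set.seed(seed)
  test_idx <- sort(c(
    sample(mono1, 1), sample(mono2, 1), sample(grid, 5)
  ))
  new_split(data, test_idx, "dream_6x6", seed)
}

#' @rdname split_dream
#' @export
split_almanac <- function(data, seed = 1L) {
  stopifnot(inherits(data, "dose_response"))
  if (dr_setting(data) != "combo") {
    abort("split_almanac() needs a combination matrix (15-point layout).")
  }
  base <- which(data$dose1 == 0 & data$dose2 == 0)
  mono1 <- which(data$dose1 > 0 & data$dose2 == 0)
  mono2 <- which(data$dose1 == 0 & data$dose2 > 0)
  grid <- which(data$dose1 > 0 & data$dose2 > 0)
  if (length(base) != 1 || length(mono1) != 3 || length(mono2) != 3 ||
    length(grid) != 9) {
    abort(paste0(
      "expected the 15-point layout (1 base + 3 + 3 monotherapy + 9 grid points); got ",
      length(base), " + ", length(mono1), " + ", length(mono2), " + ", length(grid), "."
    ))
  }
  set.seed(seed)
  test_idx <- sort(sample(c(mono1, mono2, grid), 3))
  new_split(data, test_idx, "almanac_15", seed)
}

#' @rdname split_dream
#' @export
split_fraction <- function(data, fraction = 0.2, seed = 1L) {
  stopifnot(inherits(data, "dose_response"), fraction > 0, fraction < 1)
  doses <- as.matrix(as_tibble(data)[grep("^dose", names(data))])
  nonbase <- which(rowSums(doses) > 0)
  n_test <- max(1, round(fraction * length(nonbase)))
  if (n_test >= length(nonbase)) abort("fraction leaves no non-base training point.")
  set.seed(seed)
  test_idx <- sort(sample(nonbase, n_test))
  new_split(data, test_idx, "fraction", seed)
}

new_split <- function(data, test_idx, strategy, seed) {
  structure(
    list(
      train = dr_slice(data, setdiff(seq_len(nrow(data)), test_idx)),
      test = dr_slice(data, test_idx),
      strategy = strategy, seed = as.integer(seed), test_idx = test_idx
    ),
    class = "dr_split"
  )
}

#' @export
print.dr_split <- function(x, ...) {
  cat(sprintf(
    "<dr_split: %s, %d train / %d test points (seed %d)>\n",
    x$strategy, nrow(x$train), nrow(x$test), x$seed
  ))
  invisible(x)
}
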