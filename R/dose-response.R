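#' Construct a dose-response dataset
#'
#' Builds the container used throughout the package from a plain data frame of
#' measurements. Monotherapy data have columns `dose` (or `dose1`) and
#' `response`; two-drug combination data have `dose1`, `dose2` and `response`.
#' Replicates at the same dose are kept as distinct rows. Responses live on a
#' normalised inhibition scale where the dose-zero base value is approximately
#' `B` (100 under the DREAM screening convention) and a fully effective drug
#' drives the response towards 0.
#'
#' Unlike [read_dose_response()], which enforces the screening-data filtering
#' rules (no negative responses, at least one strictly positive dose), this
#' constructor only warns on such data so that synthetic datasets — where the
#' Gaussian noise model can legitimately produce negative values — and
#' degenerate prior-checking fixtures remain representable.
#'
#' @param data A data frame with columns `dose`/`dose1` (+ optional `dose2`)
#'   and `response`.
#' @param B Base response at dose zero used for normalisation (default 100).
#' @param drug_names Optional character vector of drug labels (length 1 or 2).
#' @return A tibble of class `dose_response` with columns `dose1`
#'   (+ `dose2` for combinations) and `response`, carrying `B`, `setting`
#'   (`"mono"` or `"combo"`) and `drug_names` as attributes.
#' @examples
#' dose_response(data.frame(dose = c(0, 1, 10), response = c(99, 60, 20)))
#' @export
dose_response <- function(data, B = 100, drug_names = NULL) {
  data <- as_tibble(data)
  if ("dose" %in% names(data) && !"dose1" %in% names(data)) {
    data <- dplyr::rename(data, dose1 = "dose")
  }
  if (!all(c("dose1", "response") %in% names(data))) {
    abort("`data` must have columns `dose`/`dose1` and `response`.")
  }
  setting <- if ("dose2" %in% names(data)) "combo" else "mono"
  cols <- c("dose1", if (setting == "combo") "dose2", "response")
  data <- data[cols]
  doses <- as.matrix(data[setdiff(cols, "response")])
  if (anyNA(data) || !all(is.finite(as.matrix(data)))) {
    abort("doses and responses must be finite and non-missing.")
  }
  if (any(doses < 0)) abort("doses must be non-negative.")
  if (nrow(data) == 0) abort("dataset is empty.")
  if (!any(rowSums(doses) > 0)) {
    warn("dataset has no strictly positive dose; only the base level is informed.")
  }
  if (any(data$response < 0)) {
    warn("dataset contains negative responses; screening loaders reject these.")
  }
  stopifnot(is.numeric(B), length(B) == 1, B > 0)
  structure(data,
    class = c("dose_response", class(data)),
    B = B, setting = setting, drug_names = drug_names
  )
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "<dose_response: %s, %d points, B = %g>\n",
    dr_setting(x), nrow(x), dr_base(x)
  ))
  NextMethod()
}

#' Setting and base value of a dose-response dataset
#'
#' @param x A [dose_response()] object.
#' @return `dr_setting()` returns `"mono"` or `"combo"`; `dr_base()` the base
#'   response `B`.
#' @export
dr_setting <- function(x) attr(x, "setting")

#' @rdname dr_setting
#' @export
dr_base <- function(x) attr(x, "B")

# canonical fingerprint used to guard against train/test contamination
dr_hash <- function(x) {
  tab <- as.data.frame(x)
  tab <- tab[do.call(order, unname(tab)), , drop = FALSE]
  rlang::hash(list(round(as.matrix(tab), 10), dr_base(x)))
}

# subset rows, keeping class and attributes; the parent dataset was already
# validated, so degenerate-data warnings are not repeated here
dr_slice <- function(x, idx) {
  out <- as_tibble(x)[idx, , drop = FALSE]
  suppressWarnings(
    dose_response(out, B = dr_base(x), drug_names = attr(x, "drug_names"))
  )
}

#' Read a dose-response CSV
#'
#' Two dialects are supported. The long format has a header
#' `dose1,dose2,response` (the `dose2` column may be absent or named `dose`
#' for monotherapy). The wide format mirrors the usual screening matrix
#' layout: the header row holds the doses of drug 1, the first column the
#' doses of drug 2 (both including 0), and the body the responses, so the
#' top-left body cell is the base value measured at dose (0, 0).
#'
#' Screening-data filtering rules are enforced here: rows with negative
#' responses are rejected (such wells are removed from the public screens
#' before modelling), the base cell must appear exactly once in the wide
#' format, and at least one strictly positive dose must be present.
#'
#' @param path Path to a CSV file.
#' @param format `"long"`, `"wide"`, or `"auto"` (detect from the header).
#' @param B Base response value for normalisation metadata.
#' @param drug_names Optional drug labels.
#' @return A [dose_response()] tibble.
#' @seealso [write_dose_response()]
#' @export
read_dose_response <- function(path, format = c("auto", "long", "wide"),
                               B = 100, drug_names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    hdr <- names(read.csv(path, nrows = 1, check.names = FALSE))
    format <- if (any(c("dose", "dose1") %in% hdr)) "long" else "wide"
  }
  if (format == "long") {
    raw <- read.csv(path, check.names = FALSE)
    if ("dose" %in% names(raw) && !"dose1" %in% names(raw)) {
      names(raw)[names(raw) == "dose"] <- "dose1"
    }
    if (!all(c("dose1", "response") %in% names(raw))) {
      abort(sprintf("malformed header in %s: need dose/dose1 and response columns", path))
    }
  } else {
    m <- as.matrix(read.csv(path, check.names = FALSE, row.names = 1))
    d1 <- as.numeric(colnames(m))
    d2 <- as.numeric(rownames(m))
    if (anyNA(d1) || anyNA(d2)) {
      abort(sprintf("malformed wide-format header in %s: dose labels must be numeric", path))
    }
    if (sum(d1 == 0) != 1 || sum(d2 == 0) != 1) {
      abort(sprintf("wide format in %s must contain the base cell (dose 0, 0) exactly once", path))
    }
    raw <- expand.grid(dose2 = d2, dose1 = d1)
    raw$response <- as.vector(m)
    raw <- raw[c("dose1", "dose2", "response")]
  }
  bad <- which(raw$response < 0)
  if (length(bad)) {
    abort(sprintf(
      "negative responses are removed from screening data before modelling; offending row(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  doses <- raw[grep("^dose", names(raw))]
  if (!any(rowSums(as.matrix(doses)) > 0)) {
    abort(sprintf("%s contains no strictly positive dose", path))
  }
  dose_response(raw, B = B, drug_names = drug_names)
}

#' Write a dose-response dataset to CSV
#'
#' Inverse of [read_dose_response()]: `parse(write(x))` returns the same
#' points in both dialects. The wide dialect requires a complete grid (every
#' dose1/dose2 combination measured exactly once), which is what screening
#' matrices provide.
#'
#' @param x A [dose_response()] object.
#' @param path Output CSV path.
#' @param format `"long"` (default) or `"wide"` (combination grids only).
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    if (dr_setting(x) != "combo") abort("wide format requires combination data.")
    d1 <- sort(unique(x$dose1))
    d2 <- sort(unique(x$dose2))
    wide <- tidyr::pivot_wider(
      dplyr::arrange(as_tibble(x), .data$dose2, .data$dose1),
      names_from = "dose1", values_from = "response"
    )
    if (anyNA(wide) || nrow(x) != length(d1) * length(d2)) {
      abort("wide format requires a complete, replicate-free dose grid.")
    }
    m <- as.data.frame(wide[, -1])
    rownames(m) <- wide$dose2
    write.csv(m, path, row.names = TRUE)
  }
  invisible(path)
}
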