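#' Published transport and binding data for the dithioureidodecalin series
#'
#' The measured per-transporter quantities for the six n-alkyl-substituted
#' dithioureidodecalin carriers 7a--7f (R = H, Et, Bu, Hex, Oct, Dec):
#' calculated logP, chloride association constants in chloroform and wet
#' DMSO, chloride-influx initial rates at transporter/lipid 1:2500 and
#' 1:1000, and the reported specific initial rate. These printed values are
#' inputs to the reproduction of the activity trend (the specific initial
#' rate peaks at the hexyl transporter 7d).
#'
#' @return data.frame with one row per transporter.
#' @export
decalinTransportData <- function() {
  path <- system.file("extdata", "table1_transport.csv", package = "anophore",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a per-transporter summary table
#'
#' One row per transporter: binding constant (when fitted), the initial rate
#' of each contributing experiment, and the specific initial rate, with the
#' maximal-activity row flagged. Rows are sorted by transporter label so the
#' table is invariant to input order.
#'
#' @param kinetics named list (by transporter label) of data.frames with
#'   columns `ratio` and `initial_rate`, or of `specificRate` objects.
#' @param binding optional named list (by label) of `bindingFit` objects or
#'   numeric Ka values.
#' @return a `summaryTable` data.frame with columns `transporter`, `Ka`,
#'   `n_experiments`, `I`, `I_sem`, `is_max`.
#' @export
buildSummaryTable <- function(kinetics, binding = NULL) {
  labels <- names(kinetics)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("kinetics must be a named list keyed by transporter label", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate transporter labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(labels, function(lab) {
    k <- kinetics[[lab]]
    sr <- if (inherits(k, "specificRate")) k else specificInitialRate(k)
    ka <- NA_real_
    if (!is.null(binding) && lab %in% names(binding)) {
      b <- binding[[lab]]
      ka <- if (inherits(b, "bindingFit")) b$Ka else as.numeric(b)
    }
    data.frame(transporter = lab, Ka = ka,
               n_experiments = nrow(sr$experiments),
               I = sr$I, I_sem = sr$sem, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transporter), , drop = FALSE]
  rownames(out) <- NULL
  out$is_max <- seq_len(nrow(out)) == which.max(out$I)
  class(out) <- c("summaryTable", "data.frame")
  out
}

#' @export
print.summaryTable <- function(x, ...) {
  cat("Transporter activity summary (", nrow(x), " transporters)\n", sep = "")
  df <- as.data.frame(x)
  df$I <- sprintf("%.2f", df$I)
  df$Ka <- ifelse(is.na(df$Ka), "-", sprintf("%.3g", df$Ka))
  print(df, row.names = FALSE)
  cat("maximal activity:", x$transporter[x$is_max], "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero
#' (the convention used when comparing computed rates with values printed to
#' a fixed precision), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Write analysis summaries as JSON
#'
#' Serialises average positions, orientation calls, events, kinetic or
#' binding fits (any list-like result object) to a JSON file.
#'
#' @param x result object (list-like).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryJSON <- function(x, path) {
  x <- unclass(x)
  drop <- vapply(x, function(el) is.data.frame(el) && nrow(el) > 10000, logical(1))
  jsonlite::write_json(x[!drop], path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
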