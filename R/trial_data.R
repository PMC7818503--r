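#' Construct a meta-analysis dataset of two-arm binary-outcome trials
#'
#' Bundles per-trial 2x2 tables (events and sample sizes in the treatment
#' and control arm) into a validated data frame of class
#' \code{"meta_dataset"}.  Zero-event arms and double-zero trials are
#' legitimate data and are retained: the binomial likelihood used by
#' \code{\link{bnhm}} needs no continuity correction.
#'
#' @param label character vector of unique trial identifiers.
#' @param r_t integer vector, event counts in the treatment arm.
#' @param n_t integer vector, sample sizes in the treatment arm.
#' @param r_c integer vector, event counts in the control arm.
#' @param n_c integer vector, sample sizes in the control arm.
#'
#' @return A data frame with columns \code{label}, \code{r_t}, \code{n_t},
#'   \code{r_c}, \code{n_c} and class \code{c("meta_dataset", "data.frame")}.
#' @examples
#' meta_dataset(c("t1", "t2"), r_t = c(0, 3), n_t = c(5, 6),
#'              r_c = c(0, 0), n_c = c(5, 6))
#' @export
meta_dataset <- function(label, r_t, n_t, r_c, n_c) {
  label <- as.character(label)
  k <- length(label)
  if (k < 1L) stop("a meta-analysis dataset needs at least one trial")
  counts <- list(r_t = r_t, n_t = n_t, r_c = r_c, n_c = n_c)
  if (any(lengths(counts) != k)) {
    stop("label and count vectors must have equal length")
  }
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (any(!is.finite(v)) || any(abs(v - round(v)) > 1e-8)) {
      stop("column '", nm, "' must contain finite integer counts")
    }
    counts[[nm]] <- as.integer(round(v))
  }
  d <- data.frame(label = label, counts, stringsAsFactors = FALSE)
  bad <- which(d$r_t < 0L | d$r_c < 0L | d$n_t < 1L | d$n_c < 1L |
                 d$r_t > d$n_t | d$r_c > d$n_c)
  if (length(bad)) {
    stop("invalid counts (need 0 <= r <= n, n >= 1) in row ", bad[1L],
         " ('", d$label[bad[1L]], "')")
  }
  if (anyDuplicated(d$label)) {
    stop("trial labels must be unique within a dataset")
  }
  class(d) <- c("meta_dataset", "data.frame")
  d
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("Meta-analysis dataset:", nrow(x), "trial(s),",
      sum(x$r_t), "treatment events /", sum(x$n_t), "patients,",
      sum(x$r_c), "control events /", sum(x$n_c), "patients\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Number of trials in a dataset
#'
#' @param data a \code{\link{meta_dataset}}.
#' @return Integer count of trials.
#' @export
n_trials <- function(data) {
  stopifnot(inherits(data, "meta_dataset"))
  nrow(data)
}

#' Read a meta-analysis dataset from a CSV file
#'
#' The file must have a header \code{label,r_t,m_t,r_c,m_c}.  The
#' \code{m_*} columns hold either non-event counts (\code{counts =
#' "nonevents"}, the convention in which published 2x2 tables are often
#' printed) or arm sample sizes (\code{counts = "n"}).
#'
#' @param path path to a CSV file.
#' @param counts whether the \code{m_*} columns are non-events (default)
#'   or total sample sizes.
#' @return A \code{\link{meta_dataset}}.
#' @seealso \code{\link{write_meta_csv}}, \code{\link{mmn_trials}}
#' @export
read_meta_csv <- function(path, counts = c("nonevents", "n")) {
  counts <- match.arg(counts)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "r_t", "m_t", "r_c", "m_c")
  if (!all(need %in% names(d))) {
    stop("file '", path, "' must have columns ", paste(need, collapse = ", "))
  }
  n_t <- if (counts == "nonevents") d$r_t + d$m_t else d$m_t
  n_c <- if (counts == "nonevents") d$r_c + d$m_c else d$m_c
  meta_dataset(d$label, r_t = d$r_t, n_t = n_t, r_c = d$r_c, n_c = n_c)
}

#' Write a meta-analysis dataset to CSV
#'
#' @inheritParams read_meta_csv
#' @param data a \code{\link{meta_dataset}}.
#' @return \code{path}, invisibly.
#' @export
write_meta_csv <- function(data, path, counts = c("nonevents", "n")) {
  counts <- match.arg(counts)
  stopifnot(inherits(data, "meta_dataset"))
  out <- data.frame(
    label = data$label,
    r_t = data$r_t,
    m_t = if (counts == "nonevents") data$n_t - data$r_t else data$n_t,
    r_c = data$r_c,
    m_c = if (counts == "nonevents") data$n_c - data$r_c else data$n_c
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pooled observed event probability per trial
#'
#' The events of both arms divided by the total number of patients,
#' \eqn{(r_T + r_C) / (n_T + n_C)}; a crude sparseness indicator that is
#' symmetric in the arms.
#'
#' @param data a \code{\link{meta_dataset}}.
#' @return Named numeric vector of proportions in \[0, 1\].
#' @examples
#' observed_event_prob(mmn_trials())
#' @export
observed_event_prob <- function(data) {
  stopifnot(inherits(data, "meta_dataset"))
  stats::setNames((data$r_t + data$r_c) / (data$n_t + data$n_c), data$label)
}

#' Within-study variances of the log odds ratio
#'
#' The usual large-sample variance \eqn{1/a + 1/b + 1/c + 1/d} of the
#' per-trial log odds ratio, where (a, b, c, d) are the four cells of the
#' 2x2 table.  For any trial containing at least one zero cell the
#' correction constant is added to all four of its cells; trials without
#' zero cells are left uncorrected.  These variances are used only to set
#' the scale s0 of the empirical heterogeneity priors (see
#' \code{\link{compute_s0}}); the model likelihood never uses them.
#'
#' @param data a \code{\link{meta_dataset}}.
#' @param correction non-negative constant added to the cells of
#'   zero-cell trials (default 0.5).
#' @return Named numeric vector of variances on the squared-logOR scale.
#' @export
within_variances <- function(data, correction = 0.5) {
  stopifnot(inherits(data, "meta_dataset"), correction >= 0)
  a <- data$r_t
  b <- data$n_t - data$r_t
  c_ <- data$r_c
  d <- data$n_c - data$r_c
  has_zero <- (a == 0L) | (b == 0L) | (c_ == 0L) | (d == 0L)
  if (correction == 0 && any(has_zero)) {
    stop("dataset contains zero cells (e.g. trial '",
         data$label[which(has_zero)[1L]],
         "'); supply a positive continuity correction to compute ",
         "within-study variances")
  }
  cc <- ifelse(has_zero, correction, 0)
  s2 <- 1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc)
  stats::setNames(s2, data$label)
}

#' Case-study dataset: multifocal motor neuropathy
#'
#' Three small randomized trials of intravenous immunoglobulin versus
#' placebo in multifocal motor neuropathy (outcome: improvement in
#' disability).  One trial has zero events in both arms.
#'
#' @return A \code{\link{meta_dataset}} with 3 trials.
#' @export
mmn_trials <- function() {
  read_meta_csv(system.file("extdata", "mmn.csv", package = "bnhm"),
                counts = "nonevents")
}

#' Case-study dataset: Guillain-Barre syndrome
#'
#' Four randomized trials of intravenous immunoglobulin versus plasma
#' exchange in Guillain-Barre syndrome (outcome: treatment
#' discontinuation, where fewer events favour treatment).  Two trials
#' have zero-event treatment arms, one of them zero events in both arms.
#'
#' @return A \code{\link{meta_dataset}} with 4 trials.
#' @export
gbs_trials <- function() {
  read_meta_csv(system.file("extdata", "gbs.csv", package = "bnhm"),
                counts = "nonevents")
}
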