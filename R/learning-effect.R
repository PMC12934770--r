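#' Mixed-effects test of learning effects on a time course
#'
#' Fits linear mixed-effects regressions of a measured quantity (ensemble
#' engagement or a DDM parameter, in long format) on time, learning stage
#' (number of training trials) and trajectory type, with a random intercept
#' per network.  Both a linear and a quadratic (time + time^2) model are
#' fitted with maximum likelihood; the one with the lower BIC is selected.
#' Reported are the interaction p-values involving learning and type
#' (time x learning, time x type, time x learning x type, plus quadratic
#' counterparts when the quadratic model is selected), with a Bonferroni
#' threshold alpha / n_classes for the full-trajectory test.
#'
#' @param table data frame with columns \code{network_id},
#'   \code{trajectory_type}, \code{learning_stage}, \code{time_bin},
#'   \code{value}.
#' @param alpha base significance level (default 0.05).
#' @param n_classes number of decision classes analysed in parallel
#'   (Bonferroni divisor; default 4, giving 0.05 / 4 = 0.0125).
#' @return A \code{learning_effect}: list with \code{selected}
#'   (\code{"linear"} or \code{"quadratic"}), \code{bic} (both models),
#'   \code{p_interactions} (named), \code{significant} flags at the
#'   corrected threshold, \code{threshold}, and \code{singular} flag.
#' @export
fit_learning_model <- function(table, alpha = 0.05, n_classes = 4L) {
  req <- c("network_id", "trajectory_type", "learning_stage", "time_bin",
           "value")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "))
  if (length(unique(table$learning_stage)) < 2L)
    stop("need at least two learning stages")
  if (length(unique(table$network_id)) < 2L)
    stop("need at least two networks")
  d <- data.frame(
    value = table$value,
    time = as.numeric(table$time_bin),
    stage = as.numeric(table$learning_stage),
    type = factor(table$trajectory_type),
    network = factor(table$network_id))
  one_type <- nlevels(d$type) < 2L

  form_lin <- if (one_type) value ~ time * stage + (1 | network)
              else value ~ time * stage * type + (1 | network)
  form_quad <- if (one_type)
    value ~ (time + I(time^2)) * stage + (1 | network)
  else value ~ (time + I(time^2)) * stage * type + (1 | network)

  fit_one <- function(form) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d, REML = FALSE)))
  }
  m_lin <- fit_one(form_lin)
  m_quad <- fit_one(form_quad)
  bic <- c(linear = stats::BIC(m_lin), quadratic = stats::BIC(m_quad))
  selected <- names(bic)[which.min(bic)]
  m <- if (selected == "linear") m_lin else m_quad

  co <- stats::coef(summary(m))
  pcol <- grep("^Pr", colnames(co), value = TRUE)[1L]
  want <- c("time:stage", "time:type", "time:stage:type",
            "I(time^2):stage", "I(time^2):type", "I(time^2):stage:type")
  norm_term <- function(x) gsub("type[^:]*", "type", x)
  terms_norm <- norm_term(rownames(co))
  p <- stats::setNames(rep(NA_real_, length(want)), want)
  for (w in want) {
    hit <- which(terms_norm == w)
    if (length(hit) > 0L) p[w] <- min(co[hit, pcol])  # worst-case contrast
  }
  p <- p[!is.na(p)]
  threshold <- alpha / n_classes
  structure(list(
    selected = selected, bic = bic,
    p_interactions = p,
    significant = p < threshold,
    threshold = threshold, alpha = alpha,
    singular = lme4::isSingular(m),
    model = m
  ), class = "learning_effect")
}

#' @export
print.learning_effect <- function(x, ...) {
  cat(sprintf("Learning-effect mixed model (%s selected; threshold %.4f)\n",
              x$selected, x$threshold))
  print(data.frame(term = names(x$p_interactions),
                   p = signif(x$p_interactions, 3),
                   significant = x$significant, row.names = NULL))
  if (x$singular) cat("  [random-effect fit singular]\n")
  invisible(x)
}

#' Pointwise follow-up of a significant learning effect
#'
#' After a significant full-trajectory interaction, tests the learning
#' effect at each time bin separately (random intercept per network; the
#' per-bin fixed-effect structure mirrors the terms found significant in
#' the omnibus model) at the uncorrected level alpha = 0.05, and returns
#' the contiguous significant windows.
#'
#' @param table the long table passed to \code{\link{fit_learning_model}}.
#' @param report the \code{learning_effect} from the omnibus fit.
#' @param alpha pointwise significance level.
#' @return A list with \code{per_bin} (data frame \code{time_bin},
#'   \code{p}, \code{significant}) and \code{windows} (data frame
#'   \code{from}, \code{to} of contiguous significant runs).
#' @export
pointwise_followup <- function(table, report, alpha = 0.05) {
  if (!inherits(report, "learning_effect"))
    stop("report must come from fit_learning_model")
  if (!any(report$significant))
    stop("omnibus test not significant; pointwise follow-up not run")
  use_type <- any(grepl("type", names(report$p_interactions)[report$significant]))
  bins <- sort(unique(table$time_bin))
  p <- vapply(bins, function(b) {
    d <- table[table$time_bin == b, ]
    d <- data.frame(value = d$value, stage = as.numeric(d$learning_stage),
                    type = factor(d$trajectory_type),
                    network = factor(d$network_id))
    form <- if (use_type && nlevels(d$type) > 1L)
      value ~ stage * type + (1 | network)
    else value ~ stage + (1 | network)
    m <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = d, REML = FALSE))),
      error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    co <- stats::coef(summary(m))
    pcol <- grep("^Pr", colnames(co), value = TRUE)[1L]
    rows <- grep("stage", rownames(co))
    min(co[rows, pcol])
  }, numeric(1))
  sig <- !is.na(p) & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  windows <- data.frame(from = bins[starts[r$values]],
                        to = bins[ends[r$values]])
  list(per_bin = data.frame(time_bin = bins, p = p, significant = sig),
       windows = windows, alpha = alpha)
}
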