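#' Shannon entropy of a discrete distribution, in bits
#'
#' \eqn{H = -\sum_s p_s \log_2 p_s} with \eqn{0 \log 0 = 0}.
#'
#' @param p Probability vector (or a `bbn_distribution`).
#' @return Entropy in bits.
#' @examples
#' entropy_bits(c(0.5, 0.5))     # 1 bit
#' entropy_bits(c(0.0307, 0.9693))
#' @export
entropy_bits <- function(p) {
  if (inherits(p, "bbn_distribution")) p <- p$p
  p <- as.numeric(p)
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) stop("not a valid distribution")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Association screen of every covariate against the target
#'
#' For each non-target variable, computes (on the pairwise complete cases):
#' mutual information with the target in bits; normalized MI as a
#' percentage of the target's maximum entropy `log2(r_target)` (for a
#' binary target this is just 100*MI); relative MI as a percentage of the
#' target's actual entropy; Pearson correlation on the canonical integer
#' state codes (target coded 0/1); degrees of freedom
#' `(r_x - 1)(r_target - 1)`; and the G-test p-value with
#' `G = 2 N ln(2) MI` referred to the upper chi-square tail. Rows are
#' sorted by MI, descending. A constant covariate gets MI 0 and an
#' undefined correlation reported as 0 with `flag = "constant"`.
#'
#' @param ds A `bbn_dataset`.
#' @param target Target variable name.
#' @return data.frame with columns `node`, `mutual_information`,
#'   `normalized_mi_pct`, `relative_mi_pct`, `pearson_r`, `df`, `p_value`,
#'   `flag`.
#' @export
association_table <- function(ds, target) {
  if (!target %in% schema_names(ds$schema))
    stop("unknown target '", target, "'")
  cards <- schema_cards(ds$schema)
  rt <- cards[[target]]
  rows <- lapply(setdiff(schema_names(ds$schema), target), function(v) {
    ct <- contingency_counts(ds, c(v, target))
    mi <- mutual_information(ct)
    arr <- ct_array(ct)
    ht <- entropy_counts(colSums(arr))
    flag <- ""
    marg_x <- rowSums(arr)
    if (sum(marg_x > 0) < 2L) {
      mi <- 0
      r <- 0
      flag <- "constant"
    } else {
      # weighted Pearson on 0-based integer codes
      grid <- config_grid(ct$cards)
      w <- ct$counts
      cx <- grid[, 1] - 1
      cy <- grid[, 2] - 1
      mx <- sum(w * cx) / ct$n
      my <- sum(w * cy) / ct$n
      sx <- sqrt(sum(w * (cx - mx)^2) / ct$n)
      sy <- sqrt(sum(w * (cy - my)^2) / ct$n)
      r <- if (sx == 0 || sy == 0) {
        flag <- "constant"
        0
      } else sum(w * (cx - mx) * (cy - my)) / (ct$n * sx * sy)
    }
    df <- (cards[[v]] - 1) * (rt - 1)
    g <- 2 * ct$n * log(2) * mi
    data.frame(node = v,
               mutual_information = mi,
               normalized_mi_pct = 100 * mi / log2(rt),
               relative_mi_pct = if (ht > 0) 100 * mi / ht else 0,
               pearson_r = r,
               df = df,
               p_value = stats::pchisq(g, df, lower.tail = FALSE),
               flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mutual_information, out$node), , drop = FALSE]
}

#' Score and classify records under a network
#'
#' For each complete record, computes the exact posterior of the target
#' given all features (which for a TAN reduces to
#' \eqn{P(c \mid x) \propto P(c) \prod_i P(x_i \mid pa(x_i), c)}) and
#' returns the positive-state probability plus the MAP prediction (ties
#' resolved to the first state).
#'
#' @param net A valid `bbn_net`.
#' @param ds A complete `bbn_dataset` (impute first; missing cells are an
#'   error).
#' @param target Target variable name.
#' @param positive Positive state label for the score column (default the
#'   target's last state).
#' @return data.frame with columns `score` (P(positive | features)) and
#'   `prediction` (state label).
#' @export
classify <- function(net, ds, target, positive = NULL) {
  assert_valid_net(net)
  states <- schema_states(net$schema, target)
  positive <- positive %||% states[length(states)]
  pos_idx <- match(positive, states)
  if (is.na(pos_idx)) stop("unknown positive state '", positive, "'")
  x <- ds$x
  feat_missing <- is.na(x[, setdiff(colnames(x), target), drop = FALSE])
  if (any(feat_missing))
    stop("dataset has missing feature cells; run impute_missing() first")
  lp <- matrix(NA_real_, nrow(x), length(states))
  for (t in seq_along(states)) {
    x[, target] <- t
    lp[, t] <- log2_joint_records(net, x)
  }
  mx <- apply(lp, 1, max)
  w <- 2^(lp - mx)
  w[!is.finite(w)] <- 0
  post <- w / rowSums(w)
  data.frame(score = post[, pos_idx],
             prediction = states[max.col(post, ties.method = "first")],
             stringsAsFactors = FALSE)
}

auc_midrank <- function(truth_pos, scores) {
  n1 <- sum(truth_pos)
  n0 <- sum(!truth_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the cumulative-gains curve (fraction of positives captured
# vs fraction of records screened, best-scored first), by trapezoid over
# the per-record step points.
gains_area <- function(truth_pos, scores) {
  n <- length(scores)
  ord <- order(-scores)
  hits <- cumsum(truth_pos[ord]) / sum(truth_pos)
  xs <- seq_len(n) / n
  sum((hits + c(0, utils::head(hits, -1))) / 2 * (xs - c(0, utils::head(xs, -1))))
}

#' Classifier validation report
#'
#' Computes, as percentages: overall precision (share of records whose MAP
#' prediction is correct); reliability (truth-weighted mean of per-class
#' predictive values, i.e. \eqn{\sum_k (n_k/n)\, PPV_k}); ROC index (AUC
#' of the positive-class scores, midranks for ties); and lift index (area
#' under the model's cumulative-gains curve as a share of the ideal
#' ranking's area). With single-class truth the ROC and lift indices are
#' undefined and reported as `NA` with a flag.
#'
#' @param truth Vector of true state labels.
#' @param predictions Vector of predicted state labels, same length.
#' @param scores Numeric positive-class scores, same length.
#' @param positive Positive state label (default: last level of `truth`'s
#'   sorted unique values).
#' @return Object of class `bbn_validation`: `confusion` (true x
#'   predicted), `precision_pct`, `reliability_pct`, `roc_index_pct`,
#'   `lift_index_pct`, `n`, `flag`.
#' @export
validation_metrics <- function(truth, predictions, scores, positive = NULL) {
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  n <- length(truth)
  stopifnot(n >= 1L, length(predictions) == n, length(scores) == n)
  classes <- sort(unique(c(truth, predictions)))
  positive <- positive %||% classes[length(classes)]
  confusion <- table(truth = factor(truth, classes),
                     predicted = factor(predictions, classes))
  precision <- 100 * sum(diag(confusion)) / n
  n_true <- rowSums(confusion)
  n_pred <- colSums(confusion)
  ppv <- ifelse(n_pred > 0, diag(confusion) / n_pred, 0)
  reliability <- 100 * sum((n_true / n) * ppv)
  flag <- ""
  truth_pos <- truth == positive
  if (length(unique(truth)) < 2L) {
    roc <- NA_real_
    lift <- NA_real_
    flag <- "single-class truth: ROC and lift undefined"
  } else {
    roc <- 100 * auc_midrank(truth_pos, scores)
    lift <- 100 * gains_area(truth_pos, scores) /
      gains_area(truth_pos, as.numeric(truth_pos))
  }
  structure(list(confusion = confusion, precision_pct = precision,
                 reliability_pct = reliability, roc_index_pct = roc,
                 lift_index_pct = lift, n = n, flag = flag),
            class = "bbn_validation")
}

#' @export
print.bbn_validation <- function(x, ...) {
  cat(sprintf(paste0("<bbn_validation> n = %d\n  precision %.2f%%  ",
                     "reliability %.2f%%  ROC index %.2f%%  lift index %.2f%%\n"),
              x$n, x$precision_pct, x$reliability_pct,
              x$roc_index_pct, x$lift_index_pct))
  if (nzchar(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Validate a network classifier on a held-out dataset
#'
#' Convenience wrapper: [classify()] the records, then compute
#' [validation_metrics()] against the observed target column.
#'
#' @inheritParams classify
#' @return A `bbn_validation`.
#' @export
validate_classifier <- function(net, ds, target, positive = NULL) {
  states <- schema_states(net$schema, target)
  if (any(is.na(ds$x[, target])))
    stop("target column has missing cells; validation needs observed truth")
  cl <- classify(net, ds, target, positive)
  validation_metrics(states[ds$x[, target]], cl$prediction, cl$score,
                     positive %||% states[length(states)])
}
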