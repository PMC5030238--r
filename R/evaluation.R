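#' Scoring extracted relations against gold annotations
#'
#' Predicted region pairs are compared with gold pairwise annotations in
#' three modes: \emph{strict} counts a prediction as a true positive only
#' when both extracted region strings fully match the annotated mentions;
#' \emph{lenient} additionally accepts partial (word-boundary substring)
#' matches; \emph{nlp} additionally credits dictionary-validated predictions
#' explicitly flagged as unannotated candidates (region pairs the pipeline
#' found and normalized but which the annotators did not mark). Gold pairs
#' are matched orderlessly -- directionality is scored separately by
#' [direction_accuracy()] over true positives only.
#'
#' @name evaluation
NULL

# round half up to 2 decimals, the convention of printed evaluation tables
.nc_round2 <- function(x) floor(x * 100 + 0.5) / 100

#' F-measure from precision and recall percentages
#'
#' Harmonic mean \code{2PR/(P+R)}, 0 when both are 0; reported to two
#' decimals (half-up).
#'
#' @param precision percentage in [0, 100].
#' @param recall percentage in [0, 100].
#' @return percentage.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 100, recall >= 0, recall <= 100)
  if (precision + recall == 0) return(0)
  .nc_round2(2 * precision * recall / (precision + recall))
}

#' Build an evaluation result from counts
#'
#' @param tp true positives.
#' @param fp false positives.
#' @param fn false negatives.
#' @param mode label ("strict", "lenient" or "nlp").
#' @return an \code{nc_eval_result}: list with counts and \code{precision},
#'   \code{recall}, \code{f} percentages (2 decimals, half-up). Precision
#'   with zero retrieved is reported as 0 with \code{undefined_precision =
#'   TRUE}.
#' @export
eval_result <- function(tp, fp, fn, mode = "strict") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  undef <- (tp + fp) == 0
  p <- if (undef) 0 else .nc_round2(100 * tp / (tp + fp))
  r <- if ((tp + fn) == 0) 0 else .nc_round2(100 * tp / (tp + fn))
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f = f_measure(p, r), mode = mode,
                 undefined_precision = undef),
            class = "nc_eval_result")
}

#' @export
print.nc_eval_result <- function(x, ...) {
  cat(sprintf("<%s evaluation> TP=%d FP=%d FN=%d  P=%.2f%% R=%.2f%% F=%.2f%%\n",
              x$mode, x$tp, x$fp, x$fn, x$precision, x$recall, x$f))
  invisible(x)
}

# gold interaction pairs as (sentence_id, mention1, mention2, direction)
.nc_gold_pairs <- function(gold) {
  p <- gold$pairs[gold$pairs$interaction, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(sentence_id = character(), m1 = character(),
                      m2 = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  etext <- stats::setNames(gold$entities$text, gold$entities$id)
  data.frame(sentence_id = p$sentence_id,
             m1 = unname(etext[p$e1]), m2 = unname(etext[p$e2]),
             direction = if ("direction" %in% names(p)) p$direction
                         else NA_character_,
             stringsAsFactors = FALSE)
}

#' Score predicted relations against a gold corpus
#'
#' A predicted pair is matched to an unused gold pair of the same sentence
#' when its two extracted surfaces align with the two annotated mentions
#' (in either order) at the quality the mode accepts: strict requires both
#' alignments to be full string matches, lenient accepts partial matches.
#' In nlp mode, unmatched predictions flagged in an
#' \code{unannotated_candidate} column are additionally counted as true
#' positives (and the false-negative count is taken against the remaining
#' gold total). Each gold pair is credited at most once.
#'
#' @param predicted relations data.frame (needs \code{doc_id},
#'   \code{sentence_index}, \code{agent_surface}, \code{target_surface};
#'   optionally \code{unannotated_candidate}).
#' @param gold an \code{nc_gold_corpus}.
#' @param mode "strict", "lenient" or "nlp".
#' @return an \code{nc_eval_result} with a \code{matches} attribute (per
#'   prediction: "tp"/"fp").
#' @export
score <- function(predicted, gold, mode = c("strict", "lenient", "nlp")) {
  mode <- match.arg(mode)
  gp <- .nc_gold_pairs(gold)
  n_gold <- nrow(gp)
  npred <- nrow(predicted)
  accept <- if (mode == "strict") "full" else c("full", "partial")

  used <- logical(n_gold)
  status <- character(npred)
  if (npred > 0L) {
    skey <- sprintf("%s.s%d", predicted$doc_id, predicted$sentence_index)
    for (i in seq_len(npred)) {
      status[i] <- "fp"
      cand <- which(!used & gp$sentence_id == skey[i])
      for (g in cand) {
        a <- predicted$agent_surface[i]; t <- predicted$target_surface[i]
        k11 <- classify_against_gold(a, gp$m1[g])
        k22 <- classify_against_gold(t, gp$m2[g])
        k12 <- classify_against_gold(a, gp$m2[g])
        k21 <- classify_against_gold(t, gp$m1[g])
        ok <- (k11 %in% accept && k22 %in% accept) ||
          (k12 %in% accept && k21 %in% accept)
        if (ok) {
          used[g] <- TRUE
          status[i] <- "tp"
          break
        }
      }
    }
  }
  tp <- sum(status == "tp")
  if (mode == "nlp" && npred > 0L &&
      "unannotated_candidate" %in% names(predicted)) {
    promote <- status == "fp" & (predicted$unannotated_candidate %in% TRUE)
    status[promote] <- "tp"
    tp <- sum(status == "tp")
  }
  fp <- sum(status == "fp")
  fn <- if (mode == "nlp") max(0L, n_gold - tp) else sum(!used)
  res <- eval_result(tp, fp, fn, mode)
  attr(res, "matches") <- status
  res
}

#' Directionality accuracy over true-positive relations
#'
#' The proportion of true-positive relations whose predicted direction
#' agrees with the gold direction; false positives are excluded. Relations
#' without a gold direction are dropped with a warning.
#'
#' @param predicted_direction character, "e1_to_e2"-style or any labels
#'   comparable with \code{gold_direction} by equality.
#' @param gold_direction same length, NA when unannotated.
#' @return an \code{nc_direction_eval}: list with \code{examined},
#'   \code{correct}, \code{accuracy} (percent, 2 decimals).
#' @export
direction_accuracy <- function(predicted_direction, gold_direction) {
  stopifnot(length(predicted_direction) == length(gold_direction))
  keep <- !is.na(gold_direction) & nzchar(gold_direction)
  if (any(!keep)) {
    warning(sum(!keep), " relation(s) without gold direction excluded",
            call. = FALSE)
  }
  pd <- predicted_direction[keep]; gd <- gold_direction[keep]
  examined <- length(pd)
  correct <- sum(pd == gd)
  acc <- if (examined == 0L) NA_real_
         else .nc_round2(100 * correct / examined)
  structure(list(examined = examined, correct = correct, accuracy = acc),
            class = "nc_direction_eval")
}

#' @export
print.nc_direction_eval <- function(x, ...) {
  cat(sprintf("<direction evaluation> %d/%d correct, accuracy %.2f%%\n",
              x$correct, x$examined, x$accuracy))
  invisible(x)
}

#' Majority-direction baseline
#'
#' Accuracy of the trivial classifier that always predicts the direction
#' running from the first brain-region mention in the sentence to the
#' second. Input is, per true-positive relation, whether the gold direction
#' actually runs first-mention to second-mention.
#'
#' @param forward logical vector (TRUE = gold direction is first mention ->
#'   second mention).
#' @return percentage (2 decimals, half-up).
#' @export
majority_direction_baseline <- function(forward) {
  stopifnot(is.logical(forward))
  forward <- forward[!is.na(forward)]
  if (length(forward) == 0L) return(NA_real_)
  .nc_round2(100 * sum(forward) / length(forward))
}
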