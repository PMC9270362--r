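#' Target-decoy q-values
#'
#' Thresholds are taken at the target scores (acceptance of the top-k
#' targets). The false discovery proportion at the k-th threshold is
#' `#(decoys >= s_k) / k`; at the lowest threshold (which accepts every
#' target) all decoys are counted, a deliberately conservative convention.
#' The q-value of a target is the minimum FDP over all thresholds at or
#' below its score (so q is monotone non-increasing in score), clipped to
#' \[0, 1\].
#'
#' @param target_scores,decoy_scores Non-empty numeric score vectors.
#' @return Numeric vector of q-values, one per target, in input order.
#' @export
compute_qvalues <- function(target_scores, decoy_scores) {
  stopifnot(length(target_scores) > 0, length(decoy_scores) > 0)
  ts <- sort(target_scores, decreasing = TRUE)
  n <- length(ts)
  D <- findInterval(-ts, sort(-decoy_scores))   # decoys >= threshold
  D[n] <- length(decoy_scores)                  # accept-all threshold
  fdp <- pmin(D / seq_len(n), 1)
  q <- rev(cummin(rev(fdp)))
  k <- findInterval(-target_scores, -ts)        # targets >= own score
  pmax(q[k], 0)
}

#' Picked-pair protein-level q-values
#'
#' Rolls precursor scores up to protein groups (protein score = best member
#' precursor score) and lets each target protein compete with its paired
#' decoy (`DECOY_<group>`): only the higher-scoring member of a pair is kept,
#' with the target winning exact ties. Q-values are then estimated over the
#' kept proteins with the [compute_qvalues()] estimator; eliminated proteins
#' and kept decoys carry `NA`.
#'
#' @param precursor_scores `data.frame` with columns `protein_group`, `score`,
#'   `decoy` (one row per scored precursor).
#' @return `data.frame` with `protein_group`, `score`, `decoy`, `picked`,
#'   `q_value`.
#' @export
protein_qvalues <- function(precursor_scores) {
  dt <- data.table::as.data.table(precursor_scores)
  prot <- dt[, .(score = max(score), decoy = decoy[1]), by = protein_group]
  base <- ifelse(prot$decoy, sub("^DECOY_", "", prot$protein_group),
                 prot$protein_group)
  ## picked competition: pair score of the partner, NA when unpaired
  tgt_score <- setNames(prot$score[!prot$decoy], base[!prot$decoy])
  dec_score <- setNames(prot$score[prot$decoy], base[prot$decoy])
  partner <- ifelse(prot$decoy, tgt_score[base], dec_score[base])
  picked <- is.na(partner) |
    ifelse(prot$decoy, prot$score > partner, prot$score >= partner)
  q_value <- rep(NA_real_, nrow(prot))
  it <- which(picked & !prot$decoy)
  id <- which(picked & prot$decoy)
  if (length(it)) {
    q_value[it] <- if (length(id))
      compute_qvalues(prot$score[it], prot$score[id]) else 0
  }
  data.frame(protein_group = prot$protein_group, score = prot$score,
             decoy = prot$decoy, picked = picked, q_value = q_value)
}
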