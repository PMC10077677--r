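# Reporter-assay and qPCR arithmetic used for in-vitro enhancer validation.

#' Luciferase activation fold change
#'
#' Firefly readings are first normalized by the Renilla co-transfection
#' control (`relative activity = firefly / renilla`), averaged per
#' condition, and the hypoxia/normal ratio of the test construct is
#' normalized by that of the empty-vector control:
#' `FC = (s_i(H) / s_i(N)) / (s_c(H) / s_c(N))`.
#'
#' Per-replicate fold changes (each replicate's H/N ratio over the control
#' mean ratio) are also returned, with their SEM and a two-sample t-test
#' against the control replicates' unit ratio.
#'
#' @param test data.frame of test-construct measurements with columns
#'   `condition` (`"H"` hypoxia / `"N"` normal), `replicate`, `firefly`,
#'   `renilla`.
#' @param control same layout for the empty-vector control.
#' @param var_equal use the equal-variance Student t-test instead of Welch
#'   when `TRUE` (default `FALSE`).
#' @return A list: `fc` (the mean-based fold change), `replicate_fc`,
#'   `sem`, `p_value`.
#' @examples
#' tst <- data.frame(condition = c("N", "H"), replicate = 1,
#'                   firefly = c(2, 8), renilla = 1)
#' ctl <- data.frame(condition = c("N", "H"), replicate = 1,
#'                   firefly = 1, renilla = 1)
#' luciferase_activation_fc(tst, ctl)$fc  # 4
#' @export
luciferase_activation_fc <- function(test, control, var_equal = FALSE) {
  check <- function(df, who) {
    stopifnot(all(c("condition", "replicate", "firefly", "renilla")
                  %in% names(df)))
    if (any(df$renilla <= 0)) stop("renilla readings must be positive")
    if (!all(c("H", "N") %in% df$condition))
      stop("missing condition in ", who, " measurements")
  }
  check(test, "test"); check(control, "control")
  rel <- function(df, cond) {
    x <- df[df$condition == cond, , drop = FALSE]
    x$firefly / x$renilla
  }
  s_iH <- rel(test, "H"); s_iN <- rel(test, "N")
  s_cH <- rel(control, "H"); s_cN <- rel(control, "N")
  fc <- (mean(s_iH) / mean(s_iN)) / (mean(s_cH) / mean(s_cN))
  # replicate-level ratios for dispersion and testing
  nrep <- min(length(s_iH), length(s_iN))
  rep_ratio <- s_iH[seq_len(nrep)] / s_iN[seq_len(nrep)]
  ctl_nrep <- min(length(s_cH), length(s_cN))
  ctl_ratio <- s_cH[seq_len(ctl_nrep)] / s_cN[seq_len(ctl_nrep)]
  rep_fc <- rep_ratio / mean(ctl_ratio)
  sem <- if (nrep > 1) stats::sd(rep_fc) / sqrt(nrep) else NA_real_
  p <- if (nrep > 1 && ctl_nrep > 1) {
    tryCatch(stats::t.test(rep_ratio, ctl_ratio,
                           var.equal = var_equal)$p.value,
             error = function(e) NA_real_)  # e.g. zero-variance replicates
  } else NA_real_
  list(fc = fc, replicate_fc = rep_fc, sem = sem, p_value = p)
}

#' Relative expression by the delta-delta-CT method
#'
#' `dCT = CT_target - CT_reference` per measurement; `ddCT` subtracts the
#' mean baseline-condition dCT; relative expression is `2^(-ddCT)`. The
#' reference gene (e.g. Gapdh) must be measured in every replicate.
#'
#' @param measurements data.frame with columns `condition`, `replicate`,
#'   `ct_target`, `ct_ref`.
#' @param baseline the baseline condition name (default `"N"`).
#' @return A list: `per_replicate` data.frame (`condition`, `replicate`,
#'   `dct`, `ddct`, `rel_expr`) and `summary` (per-condition mean and SEM
#'   of relative expression).
#' @export
ddct_relative_expression <- function(measurements, baseline = "N") {
  stopifnot(all(c("condition", "replicate", "ct_target", "ct_ref")
                %in% names(measurements)))
  if (any(!is.finite(measurements$ct_ref)))
    stop("missing reference CT")
  if (any(!is.finite(measurements$ct_target)))
    stop("CT values must be finite")
  if (!baseline %in% measurements$condition)
    stop("baseline condition absent")
  dct <- measurements$ct_target - measurements$ct_ref
  base_mean <- mean(dct[measurements$condition == baseline])
  ddct <- dct - base_mean
  rel <- 2^(-ddct)
  per <- data.frame(condition = measurements$condition,
                    replicate = measurements$replicate,
                    dct = dct, ddct = ddct, rel_expr = rel,
                    stringsAsFactors = FALSE)
  agg_mean <- tapply(rel, measurements$condition, mean)
  agg_sem <- tapply(rel, measurements$condition, function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
  list(per_replicate = per,
       summary = data.frame(condition = names(agg_mean),
                            mean_rel_expr = as.numeric(agg_mean),
                            sem = as.numeric(agg_sem),
                            stringsAsFactors = FALSE))
}
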