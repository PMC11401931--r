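# Interaction F and effect size for a two-factor within-subject design.
# y: subjects x (P*L) matrix, cells ordered period-major (p1l1, p1l2, ...).
rm_interaction_F <- function(y, P, L) {
  n <- nrow(y)
  # subject-specific interaction residuals: y_ipl - y_ip. - y_i.l + y_i..
  yp <- array(y, dim = c(n, L, P))  # [subject, layer, period]
  mi_p <- apply(yp, c(1L, 3L), mean)  # subject x period means
  mi_l <- apply(yp, c(1L, 2L), mean)  # subject x layer means
  mi <- rowMeans(y)
  r <- yp
  for (p in seq_len(P)) {
    for (l in seq_len(L)) {
      r[, l, p] <- yp[, l, p] - mi_p[, p] - mi_l[, l] + mi
    }
  }
  g <- apply(r, c(2L, 3L), mean)  # group interaction effects
  ss_int <- n * sum(g^2)
  ss_err <- sum(sweep(r, c(2L, 3L), g)^2)
  df_int <- (P - 1L) * (L - 1L)
  df_err <- (n - 1L) * df_int
  if (ss_int == 0) {
    F <- 0
    eta <- 0
  } else if (ss_err == 0) {
    F <- Inf
    eta <- 1
  } else {
    F <- (ss_int / df_int) / (ss_err / df_err)
    eta <- ss_int / (ss_int + ss_err)
  }
  list(F = F, eta_sq = eta, df = c(df_int, df_err))
}

#' Non-parametric repeated-measures ANOVA (interaction)
#'
#' Tests the period x layer interaction of a complete within-subject
#' factorial. The F statistic comes from the standard within-subject
#' decomposition (interaction mean square over its subject-by-interaction
#' error mean square); the p-value is the fraction of permutations, each
#' independently reshuffling the factorial cell labels within every subject,
#' whose F is at least the observed one. The effect size is partial eta
#' squared, `SS_interaction / (SS_interaction + SS_error)`.
#'
#' @param values data.frame with columns `subject`, `period`, `layer`,
#'   `value`; every subject must have every period x layer cell exactly once.
#' @param n_perm number of within-subject permutations.
#' @param seed integer seed.
#' @return `anova_result`: list with `F`, `eta_sq`, `p`, `df`, `n_perm`,
#'   `design`.
#' @export
perm_rm_anova <- function(values, n_perm = 10000L, seed = NULL) {
  needed <- c("subject", "period", "layer", "value")
  if (!all(needed %in% names(values))) {
    stop_ld("values needs columns ", paste(needed, collapse = ", "))
  }
  subjects <- unique(values$subject)
  periods <- sort(unique(values$period))
  layers <- sort(unique(values$layer))
  P <- length(periods); L <- length(layers)
  n <- length(subjects)
  if (n < 2L) stop_ld("need >= 2 subjects")
  y <- matrix(NA_real_, n, P * L)
  for (si in seq_len(n)) {
    for (pi in seq_len(P)) {
      for (li in seq_len(L)) {
        hit <- values$subject == subjects[si] &
          values$period == periods[pi] & values$layer == layers[li]
        if (sum(hit) != 1L) {
          stop_ld("subject ", subjects[si], " must have exactly one value in ",
                  "cell (", periods[pi], ", ", layers[li], ")")
        }
        y[si, (pi - 1L) * L + li] <- values$value[hit]
      }
    }
  }
  obs <- rm_interaction_F(y, P, L)
  with_local_seed(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) {
      yp <- y
      for (si in seq_len(n)) yp[si, ] <- y[si, sample.int(P * L)]
      rm_interaction_F(yp, P, L)$F
    }, numeric(1L))
    p <- (1 + sum(f_perm >= obs$F)) / (1 + n_perm)
    structure(list(F = obs$F, eta_sq = obs$eta_sq, p = p, df = obs$df,
                   n_perm = n_perm,
                   design = sprintf("%d periods x %d layers, within-subject",
                                    P, L)),
              class = "anova_result")
  })
}
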