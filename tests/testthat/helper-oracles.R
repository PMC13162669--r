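# Independent oracles and fixture builders. These deliberately use the
# plainest possible algorithms (explicit loops, exhaustive enumeration) so
# they share no code path with the package implementation they check.

# O(n^2) brute-force nearest-neighbor scan: distance from each source point
# to its closest target, NA when no target exists.
brute_nn <- function(sx, sy, tx, ty) {
  out <- rep(NA_real_, length(sx))
  if (!length(tx)) return(out)
  for (i in seq_along(sx)) {
    best <- Inf
    for (j in seq_along(tx)) {
      d2 <- (sx[i] - tx[j])^2 + (sy[i] - ty[j])^2
      if (d2 < best) best <- d2
    }
    out[i] <- sqrt(best)
  }
  out
}

# brute-force count of sources with squared distance to the nearest target
# <= r^2 (or < for exclusive boundaries)
brute_count_within <- function(sx, sy, tx, ty, radius, inclusive = TRUE) {
  if (!length(tx) || !length(sx)) return(0L)
  n <- 0L
  r2 <- radius^2
  for (i in seq_along(sx)) {
    best <- Inf
    for (j in seq_along(tx)) {
      d2 <- (sx[i] - tx[j])^2 + (sy[i] - ty[j])^2
      if (d2 < best) best <- d2
    }
    if (if (inclusive) best <= r2 else best < r2) n <- n + 1L
  }
  n
}

# exhaustive Mann-Whitney pair counting, ties one half
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# negative log Cox partial likelihood (Breslow; exact for tie-free data)
neg_log_pl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# two-group log-rank chi-square from first principles (hypergeometric
# mean/variance at each distinct event time)
brute_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group)) == 1L
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# build a region from explicit coordinates; marker flags consistent with the
# intended phenotype, phenotypes assigned through the default rule
make_region <- function(tam = NULL, cd8 = NULL, other = NULL,
                        width = 1000, height = 1000,
                        region_id = "R1", patient_id = "P1") {
  as_xy <- function(m) {
    if (is.null(m)) return(data.frame(x = numeric(), y = numeric()))
    m <- as.data.frame(m); names(m) <- c("x", "y"); m
  }
  tam <- as_xy(tam); cd8 <- as_xy(cd8); other <- as_xy(other)
  n <- nrow(tam) + nrow(cd8) + nrow(other)
  ph <- rep(c("PDL1_TAM", "CD8_T", "OTHER"),
            c(nrow(tam), nrow(cd8), nrow(other)))
  cells <- tibble::tibble(
    cell_id = paste0("c", seq_len(n)),
    x = c(tam$x, cd8$x, other$x), y = c(tam$y, cd8$y, other$y),
    CD8 = ph == "CD8_T", CD68 = ph == "PDL1_TAM", CD163 = FALSE,
    PDL1 = ph == "PDL1_TAM", GZMB = FALSE, TIM3 = FALSE)
  assign_phenotypes(
    region_cell_map(region_id, patient_id, width, height, cells))
}

# region with uniformly scattered phenotype counts, for property tests
random_region <- function(n_tam, n_cd8, n_other = 0, width = 400,
                          height = 400, region_id = "R1",
                          patient_id = "P1") {
  u <- function(n, lim) runif(n, 0, lim)
  make_region(tam = cbind(u(n_tam, width), u(n_tam, height)),
              cd8 = cbind(u(n_cd8, width), u(n_cd8, height)),
              other = if (n_other > 0)
                cbind(u(n_other, width), u(n_other, height)) else NULL,
              width = width, height = height,
              region_id = region_id, patient_id = patient_id)
}

cells_xy <- function(region, phenotype) {
  keep <- region$cells$phenotype == phenotype
  list(x = region$cells$x[keep], y = region$cells$y[keep])
}
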