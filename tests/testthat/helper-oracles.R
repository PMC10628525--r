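# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition with naive loops, sharing no code with the
# package implementation.

# all-pairs physical distance transform
oracle_distance <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0)
  pts <- sweep(idx, 2, spacing, `*`)
  d <- array(NA_real_, dim = dim(mask))
  dm <- dim(mask)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k) * spacing
    d[i, j, k] <- sqrt(min(colSums((t(pts) - p)^2)))
  }
  d
}

# symmetric normalized GLCM by literal pair enumeration
oracle_glcm <- function(levels, offset, n_levels) {
  dm <- dim(levels)
  cnt <- matrix(0, n_levels, n_levels)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- levels[i, j, k]
    if (a == 0) next
    ii <- i + offset[1]; jj <- j + offset[2]; kk <- k + offset[3]
    if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
    b <- levels[ii, jj, kk]
    if (b == 0) next
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# the 20 co-occurrence scalars evaluated as literal double sums
oracle_glcm_scalars <- function(P) {
  ng <- nrow(P)
  lg2 <- function(p) if (p > 0) log2(p) else 0
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:ng) mu <- mu + i * px[i]
  s2 <- 0; for (i in 1:ng) s2 <- s2 + (i - mu)^2 * px[i]
  acor <- con <- cp <- cs <- dis <- ene <- ent <- hom <- ssv <- idn <- idmn <- 0
  hxy1 <- hxy2 <- hx <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acor <- acor + i * j * p
    con <- con + (i - j)^2 * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    ent <- ent - p * lg2(p)
    hom <- hom + p / (1 + (i - j)^2)
    ssv <- ssv + (i - mu)^2 * p
    idn <- idn + p / (1 + abs(i - j) / ng)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    hxy1 <- hxy1 - p * lg2(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * lg2(px[i] * px[j])
  }
  for (i in 1:ng) hx <- hx - px[i] * lg2(px[i])
  ps <- numeric(2 * ng); pd <- numeric(ng)   # pd[k+1] = p_{x-y}(k)
  for (i in 1:ng) for (j in 1:ng) {
    ps[i + j] <- ps[i + j] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * ps[k]
  sv <- 0; for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * ps[k]
  se <- 0; for (k in 2:(2 * ng)) se <- se - ps[k] * lg2(ps[k])
  mud <- 0; for (k in 0:(ng - 1)) mud <- mud + k * pd[k + 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - mud)^2 * pd[k + 1]
  de <- 0; for (k in 0:(ng - 1)) de <- de - pd[k + 1] * lg2(pd[k + 1])
  corr <- if (s2 > 0) (acor - mu^2) / s2 else NA_real_
  imc1 <- if (hx > 0) (ent - hxy1) / hx else NA_real_
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(Autocorrelation = acor, Correlation = corr, Contrast = con,
    Cluster.Prominence = cp, Cluster.Shade = cs, Dissimilarity = dis,
    Energy = ene, Entropy = ent, Homogeneity = hom,
    Maximum.Probability = max(P), Sum.of.Squares.Variance = ssv,
    Sum.Average = sa, Sum.Variance = sv, Sum.Entropy = se,
    Difference.Variance = dv, Difference.Entropy = de, IMC1 = imc1,
    IMC2 = imc2, IDN = idn, IDMN = idmn)
}

# AUC as trapezoidal area under the empirical ROC curve
oracle_auc_trapezoid <- function(scores, labels_pos) {
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- spec <- numeric(length(th) + 2)
  sens[1] <- 0; spec[1] <- 1
  for (t in seq_along(th)) {
    pred <- scores >= th[t]
    sens[t + 1] <- sum(pred & labels_pos) / sum(labels_pos)
    spec[t + 1] <- sum(!pred & !labels_pos) / sum(!labels_pos)
  }
  sens[length(th) + 2] <- 1; spec[length(th) + 2] <- 0
  fpr <- 1 - spec
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# exhaustive pair-counting AUC
oracle_auc_pairs <- function(scores, labels_pos) {
  x <- scores[labels_pos]; y <- scores[!labels_pos]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    signs <- as.integer(intToBits(bits))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

small_cohort <- function(n_pcr = 3, n_nonpcr = 3, seed = 11, ...) {
  generate_cohort(cohort_config(
    n_pcr = n_pcr, n_nonpcr = n_nonpcr,
    image_shape = c(24L, 24L, 12L), spacing_mm = c(1, 1, 2),
    tumor_radius_range_mm = c(4, 7), seed = seed, ...))
}
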