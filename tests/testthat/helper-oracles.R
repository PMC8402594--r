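# Brute-force reference implementations used as independent oracles.

# Direct evaluation of the same-padded (optionally dilated) convolution as
# an explicit sum over kernel taps, one output element at a time.
oracle_conv <- function(x, kernel, bias = NULL, dilation = 1L) {
  k <- dim(kernel)[1]
  cin <- dim(kernel)[3]; cout <- dim(kernel)[4]
  H <- dim(x)[2]; W <- dim(x)[3]
  pad <- dilation * (k - 1) / 2
  if (is.null(bias)) bias <- numeric(cout)
  y <- array(0, dim = c(cout, H, W))
  for (co in seq_len(cout)) for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- bias[co]
    for (ci in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      sr <- r + (ki - 1) * dilation - pad
      sc <- cc + (kj - 1) * dilation - pad
      if (sr >= 1 && sr <= H && sc >= 1 && sc <= W)
        acc <- acc + kernel[ki, kj, ci, co] * x[ci, sr, sc]
    }
    y[co, r, cc] <- acc
  }
  y
}

# Per-window max scan with row-major first-occurrence tie-breaking.
oracle_pool <- function(x) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  pooled <- array(0, dim = c(C, H / 2, W / 2))
  idx <- array(0L, dim = dim(pooled))
  for (ch in seq_len(C)) for (i in seq_len(H / 2)) for (j in seq_len(W / 2)) {
    rs <- 2 * i - 1; cs <- 2 * j - 1
    cand <- rbind(c(rs, cs), c(rs, cs + 1), c(rs + 1, cs), c(rs + 1, cs + 1))
    vals <- apply(cand, 1, function(p) x[ch, p[1], p[2]])
    b <- which.max(vals)            # first max in row-major window order
    pooled[ch, i, j] <- vals[b]
    idx[ch, i, j] <- cand[b, 1] + H * (cand[b, 2] - 1)   # 1-based flat
  }
  list(pooled = pooled, indices = idx)
}

# Metric formulas computed directly from a mask pair with scalar loops.
oracle_metrics <- function(pred, truth) {
  TP <- FP <- TN <- FN <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && truth[i, j] == 1) TP <- TP + 1
    else if (pred[i, j] == 1) FP <- FP + 1
    else if (truth[i, j] == 1) FN <- FN + 1
    else TN <- TN + 1
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / (TP + FP + TN + FN),
       dice = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 1)
}

random_feature_map <- function(C, H, W) {
  array(rnorm(C * H * W), dim = c(C, H, W))
}

# A tiny in-memory training fixture (images + masks) at the given size.
make_fixture <- function(n, res, seed = 11) {
  sp <- synthetic_spec(resolution = c(res, res), seed = seed)
  recs <- lapply(seq_len(n), function(i) generate_sample(sp, i))
  list(images = lapply(recs, `[[`, "image"),
       masks = lapply(recs, `[[`, "mask"),
       records = recs)
}

# Fake pooled-dataset manifest with the study's collection sizes.
study_manifest <- function(sizes = c(clinic = 612, colon = 379, etis = 196)) {
  tibble::tibble(
    image_path = sprintf("img_%04d.png", seq_len(sum(sizes))),
    mask_path = sprintf("msk_%04d.png", seq_len(sum(sizes))),
    collection = rep(names(sizes), sizes),
    split = "unassigned")
}
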