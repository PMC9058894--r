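# shared fixtures, all generated in code

# n x n x 3 checkerboard with `block`-pixel squares, values 0/255
mk_board <- function(n, block = 4) {
  g <- outer(0:(n - 1) %/% block, 0:(n - 1) %/% block, "+") %% 2 * 255
  array(rep(g, 3), c(n, n, 3))
}

mk_const_tile <- function(value = 255, edge = 64) {
  he_tile(array(value, c(edge, edge, 3)), 0, 0, edge, edge, "const")
}

# tiles cut from a synthetic textured slide of the given class
mk_texture_tiles <- function(label, n_slides = 4, seed0 = 1, slide_px = 128,
                             tile_um = 64) {
  unlist(lapply(seq_len(n_slides), function(s) {
    sl <- make_synthetic_slide(texture_spec(label), slide_px, 1,
                               seed = seed0 + s,
                               slide_id = sprintf("s%d_%d", label, s))$slide
    tessellate(sl, tile_um, tile_um)
  }), recursive = FALSE)
}

# Beer-Lambert pixel synthesis with stain-dominant subpopulations
# (nuclei-like pure-H and stroma-like pure-E pixels plus mixtures)
mk_stain_pixels <- function(seed, n = 4000, sv = default_stain_vectors()) {
  set.seed(seed)
  grp <- sample(1:3, n, replace = TRUE, prob = c(0.15, 0.15, 0.7))
  ch <- ifelse(grp == 1, runif(n, 0.4, 1.5),
               ifelse(grp == 2, runif(n, 0, 0.03), runif(n, 0, 1.2)))
  ce <- ifelse(grp == 2, runif(n, 0.4, 1.2),
               ifelse(grp == 1, runif(n, 0, 0.03), runif(n, 0, 1.0)))
  od <- cbind(ch, ce) %*% t(sv)
  pmax(pmin(round(256 * 10^(-od) - 1), 255), 0)
}

angle_between <- function(a, b) acos(pmin(1, abs(sum(a * b))))

# exhaustive-scan oracle for the fixed-sensitivity threshold: largest
# candidate threshold (over all distinct scores) whose sensitivity under
# "positive if score >= t" still meets the target
scan_threshold_oracle <- function(score, label, target) {
  cand <- sort(unique(score[label == 1]), decreasing = TRUE)
  sens <- vapply(cand, function(t) mean(score[label == 1] >= t), numeric(1))
  cand[match(TRUE, sens >= target)]
}

# brute-force AUROC oracle over all (positive, negative) pairs
pairwise_auroc_oracle <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
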