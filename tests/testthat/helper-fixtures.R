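# Small in-code fixtures shared across test files.

tiny_starters <- function() {
  tibble::tibble(
    case_id = c("c1", "c2", "c3"),
    target_segment = c("proximal", "intermediate", "distal"),
    method = c("pressure", "pressure", "iontophoretic"),
    n_starters = c(126L, 100L, 25L))
}

tiny_counts <- function() {
  tibble::tibble(
    case_id = rep(c("c1", "c2", "c3"), each = 2),
    region = rep(c("CA3a", "SUB"), 3),
    hemisphere = "ipsilateral",
    layer = NA_character_,
    count = c(504L, 39L, 261L, 55L, 15L, 33L))
}

# movie with pure N(level, sd) noise and no structure
noise_movie <- function(frames = 120L, sd = 1, level = 1000, seed = 1L) {
  generate_vsd_movie(
    vsd_config(frames = frames, baseline_frames = 60L, noise_sd = sd,
               baseline_level = level, components = list(), artifact = NULL),
    seed = seed)
}

# deterministic movie from an explicit array
array_movie <- function(x, stim_frame = 60L, ...) {
  vsd_movie(x, stim_frame = stim_frame, ...)
}

# exhaustive two-sided permutation p-value for the Mann-Whitney U statistic
perm_mw_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - mid) >= abs(obs - mid) - 1e-9)
}
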