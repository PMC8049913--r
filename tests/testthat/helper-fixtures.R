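# Shared fixtures, all built in code at test time.

# A sample with EXACTLY the requested mean and sd (affine rescaling of a
# standardized normal draw), so printed summary statistics can be used as
# worked-example inputs.
make_sample <- function(n, mean, sd, seed = 1) {
  x <- ensemblebias:::with_seed(seed, stats::rnorm(n))
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

# The two-pair toy participant: larger/smaller reports (50, 46) and (30, 28).
toy_two_pair <- function() {
  data.frame(
    participant_id = 1L,
    pair_id = c(1L, 1L, 2L, 2L),
    context = c("larger", "smaller", "larger", "smaller"),
    true_size_px = c(48, 48, 29, 29),
    reported_size_px = c(50, 46, 30, 28)
  )
}

# A noise-free balanced table: reported == true (+ per-context offset).
noise_free_table <- function(n_participants = 3, offset_larger = 0,
                             offset_smaller = 0) {
  pd <- default_pair_designs()
  tab <- expand.grid(pair_id = pd$pair_id,
                     context = c("larger", "smaller"),
                     participant_id = seq_len(n_participants),
                     stringsAsFactors = FALSE)
  tab$true_size_px <- pd$true_size_px[match(tab$pair_id, pd$pair_id)]
  tab$reported_size_px <- tab$true_size_px +
    ifelse(tab$context == "larger", offset_larger, offset_smaller)
  tab[, c("participant_id", "pair_id", "context", "true_size_px",
          "reported_size_px")]
}
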