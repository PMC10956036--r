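# Shared fixtures: all built in code at test time.

# minimal trial table constructor
make_trials <- function(stim, resp, conf, evidence = NULL, responded = NULL) {
  n <- length(stim)
  data.frame(
    participant_id = "t01", task = "perception", block = 1L, trial = seq_len(n),
    evidence_level = if (is.null(evidence)) ifelse(stim == "right", 8L, -8L) else evidence,
    stimulus_side = stim, response_side = resp, confidence = conf,
    responded = if (is.null(responded)) !is.na(resp) else responded,
    stringsAsFactors = FALSE)
}

# rating_counts straight from a 2x2xK array
make_counts <- function(arr) {
  K <- dim(arr)[3]
  dimnames(arr) <- list(stimulus = c("left", "right"),
                        response = c("left", "right"),
                        confidence = as.character(seq_len(K)))
  structure(list(counts = arr, K = K, n_trials = sum(arr),
                 n_dropped = 0L, n_zero_evidence = 0L),
            class = "rating_counts")
}

# counts arranged to yield exact hit/fa rates with zero padding
counts_for_rates <- function(hit, fa, n_per_stim = 100L, K = 2L) {
  arr <- array(0L, dim = c(2L, 2L, K))
  arr[2, 2, 1] <- round(hit * n_per_stim)          # right | right
  arr[2, 1, 1] <- n_per_stim - arr[2, 2, 1]
  arr[1, 2, 1] <- round(fa * n_per_stim)           # right | left
  arr[1, 1, 1] <- n_per_stim - arr[1, 2, 1]
  make_counts(arr)
}

# independent grid-search oracle for the meta-d' MLE: pure likelihood
# evaluations over successively refined coordinate grids, no derivatives
grid_oracle_loglik <- function(counts, padding = 1 / (2 * counts$K),
                               rounds = 7L, pts = 15L) {
  K <- counts$K
  t1 <- type1_fit(counts, padding = padding)
  cnt <- metacogr:::.count_mats(counts$counts + padding)
  negll <- function(th) metacogr:::.metad_negll(th, K, t1$c_rel, cnt)
  npar <- 2 * K - 1
  descend <- function(centre) {
    width <- c(3, rep(2.5, npar - 1L))
    best <- negll(centre)
    for (r in seq_len(rounds)) {
      for (pass in 1:3) {
        for (j in seq_len(npar)) {
          grid <- centre[j] + seq(-width[j], width[j], length.out = pts)
          vals <- vapply(grid, function(v) {
            th <- centre; th[j] <- v; negll(th)
          }, numeric(1))
          centre[j] <- grid[which.min(vals)]
          best <- min(vals)
        }
      }
      width <- width / 2.5
    }
    best
  }
  starts <- list(c(t1$d_prime, rep(log(0.4), npar - 1L)),
                 c(t1$d_prime * 0.5, rep(log(0.9), npar - 1L)),
                 c(max(t1$d_prime, 0.5) * 1.5, rep(log(0.2), npar - 1L)))
  -min(vapply(starts, descend, numeric(1)))
}
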