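# Shared fixtures: the published mean behaviour composition, the printed
# 60-min zBMI reallocation estimates used for reconstruction, and small
# random-composition generators for property tests.

paper_base <- c(sit = 548, stand = 286, step = 107)

printed_zbmi_60 <- data.frame(
  from = c("sit", "step"), to = c("step", "sit"),
  minutes = 60, estimate = c(-0.230, 0.315))

# strictly positive random compositions in realistic minute ranges
random_compositions <- function(n, seed = 99) {
  withr::with_seed(seed, {
    m <- matrix(stats::rlnorm(3L * n, log(c(500, 280, 100)), 0.4), n, 3L,
                byrow = TRUE)
    colnames(m) <- c("sit", "stand", "step")
    m
  })
}

# an alternative valid SBP: {sit, step} vs stand, then sit vs step
alt_sbp <- function() {
  m <- matrix(c(1, -1, 1,
                1, 0, -1), nrow = 3)
  rownames(m) <- c("sit", "stand", "step")
  m
}

test_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 1524, seed = 1) {
    key <- paste0("c", n, "_", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(default_params(n = n, seed = seed))
    }
    cache[[key]]
  }
})
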