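# Shared fixture builders; everything is generated in code at test time.

# small Likert-style matrix with known bounds
likert_matrix <- function() {
  response_matrix(matrix(c(1, 4, 2,
                           5, 3, 3,
                           2, 2, 4), nrow = 3, byrow = TRUE),
                  item_min = 1, item_max = 5,
                  person_ids = c("A", "B", "C"))
}

# binary simulation with extreme (all-0 / all-1) rows removed so the
# brute-force oracle's preconditions hold
binary_no_extremes <- function(n, l, seed) {
  sim <- simulate_cir(n, l, noise = "binary", seed = seed)
  X <- sim$data$values
  keep <- !(rowSums(X) %in% c(0, ncol(X)))
  list(data = response_matrix(X[keep, , drop = FALSE], 0, 1),
       theta = sim$theta[keep], delta = sim$delta)
}

# write a small CSV fixture and return its path
write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

demo_bank <- function(n = 30) {
  item_bank(paste0("B", seq_len(n)), seq(-2, 2, length.out = n))
}
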