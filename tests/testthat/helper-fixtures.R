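# Shared fixtures, built once per test run.  Everything is generated
# in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Default-parameter core at the test scale.
fixture_core <- function(seed = 7L, size = 192L, params = stain_params()) {
  memo(sprintf("core_%d_%d_%s", seed, size,
               paste(unlist(params), collapse = "_")),
       generate_core_image(params, size, size, seed = seed))
}

# Classifier trained on 4 default cores.
fixture_classifier <- function() {
  memo("classifier", {
    train <- lapply(1:4, function(i) fixture_core(seed = i))
    train_classifier(lapply(train, `[[`, "image"),
                     lapply(train, `[[`, "truth"), seed = 99L)
  })
}

# Independent stain math for oracles: the test's own constants and its
# own inversion, sharing no code with the package internals.
oracle_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286); h <- h / sqrt(sum(h^2))
  d <- c(0.268, 0.570, 0.776); d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  cbind(h, d, r / sqrt(sum(r^2)))
}

oracle_unmix <- function(image) {
  od <- -log10((matrix(as.numeric(image), ncol = 3L) + 1) / 256)
  conc <- t(solve(oracle_stain_matrix(), t(od)))
  conc[conc < 0] <- 0
  h <- dim(image)[1]; w <- dim(image)[2]
  list(h = matrix(conc[, 1], h, w), d = matrix(conc[, 2], h, w))
}

# Seeded evaluation that restores the session RNG afterwards.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Small survival dataset used across tree/stats tests.
fixture_toy_surv <- function() {
  list(
    time = c(3, 5, 7, 2, 10, 14, 6, 1),
    event = c(1, 1, 0, 1, 0, 1, 1, 1),
    group = factor(c("a", "a", "a", "a", "b", "b", "b", "b"))
  )
}
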