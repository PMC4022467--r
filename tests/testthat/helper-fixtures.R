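# Shared fixtures: reference parameters, random parameter draws, and an
# independent matrix-exponential oracle for the linear system.

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_params <- function(k = 2L) reference_params(n_subcompartments = k)

# random positive parameter set spanning the fast/slow regimes of the model
rand_params <- function(k = sample(1:3, 1), cannulation = FALSE) {
  recirc_params(
    entry = stats::setNames(10^stats::runif(6, -3, 0.3), tissue_organs()),
    exit = stats::setNames(10^stats::runif(6, -3, 0.5), tissue_organs()),
    removal = stats::runif(1, 0, 0.005),
    dying_fraction = stats::runif(1),
    thoracic_fraction = stats::runif(1),
    n_subcompartments = k,
    cannulation = cannulation,
    exit_decline = 0
  )
}

# Independent oracle: with no exit decline the system is linear and
# time-invariant, so the solution is expm(A t) y0. The generator matrix is
# assembled here from the model's flow structure, independently of the
# compiled right-hand side.
oracle_matrix <- function(p) {
  k <- p$n_subcompartments
  nms <- c("blood", "lung", "liver_live", "liver_dead", "spleen",
           paste0("scln", seq_len(k)), paste0("mln", seq_len(k)),
           paste0("pp", seq_len(k)), "removed", "duct_collected")
  n <- length(nms)
  A <- matrix(0, n, n, dimnames = list(nms, nms))
  s <- p$entry; m <- p$exit
  mu <- p$removal; phi <- p$dying_fraction; f <- p$thoracic_fraction
  xi <- as.numeric(p$cannulation)

  A["blood", "blood"] <- -(sum(s) + mu)
  A["lung", "blood"] <- s[["lung"]]
  A["blood", "lung"] <- m[["lung"]]
  A["lung", "lung"] <- -m[["lung"]]
  A["liver_live", "blood"] <- s[["liver"]]
  A["blood", "liver_live"] <- m[["liver"]]
  A["liver_live", "liver_live"] <- -m[["liver"]]
  A["liver_dead", "blood"] <- phi * mu
  A["spleen", "blood"] <- s[["spleen"]]
  A["blood", "spleen"] <- m[["spleen"]]
  A["spleen", "spleen"] <- -m[["spleen"]]
  A["removed", "blood"] <- (1 - phi) * mu

  chain <- function(prefix, rate) {
    for (j in seq_len(k)) {
      nm <- paste0(prefix, j)
      A[nm, nm] <<- -rate
      if (j > 1) A[nm, paste0(prefix, j - 1)] <<- rate
    }
  }
  chain("scln", m[["scln"]])
  chain("mln", m[["mln"]])
  chain("pp", m[["pp"]])
  A[paste0("scln", 1), "blood"] <- s[["scln"]]
  A[paste0("mln", 1), "blood"] <- s[["mln"]]
  A[paste0("pp", 1), "blood"] <- s[["pp"]]
  A[paste0("mln", 1), paste0("pp", k)] <- m[["pp"]]

  sck <- paste0("scln", k); mk <- paste0("mln", k)
  if (xi > 0.5) {
    A["blood", sck] <- A["blood", sck] + (1 - f) * m[["scln"]]
    A["duct_collected", sck] <- f * m[["scln"]]
    A["duct_collected", mk] <- m[["mln"]]
  } else {
    A["blood", sck] <- A["blood", sck] + m[["scln"]]
    A["blood", mk] <- A["blood", mk] + m[["mln"]]
  }
  A
}

oracle_trajectory <- function(p, times) {
  A <- oracle_matrix(p)
  y0 <- numeric(nrow(A))
  y0[1] <- 100
  t(vapply(times, function(t) {
    as.numeric(Matrix::expm(A * t) %*% y0)
  }, numeric(nrow(A))))
}

# truth values of the reference set as a named vector in free-parameter order
ref_truth <- function() {
  p <- ref_params()
  c(p$entry, m_lung = 2.17, m_liver = 1.14, m_spleen = 0.007, m_ln = 0.0034,
    mu = p$removal, phi = p$dying_fraction)
}
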