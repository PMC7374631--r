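# Shared fixtures: simulated trials are cached per session so each is built
# once no matter how many tests use it.

.fixtures <- new.env(parent = emptyenv())

ref_subject <- function() {
  jumpwork:::new_subject("T01", "M", 79, 1.77, 116)
}

weak_subject <- function() {
  jumpwork:::new_subject("T02", "W", 55, 1.60, 44)
}

get_trial <- function(jump_type = "CMJ", seed = 11, subject = ref_subject(),
                      ...) {
  extra <- list(...)
  key <- paste(subject$subject_id, jump_type, seed,
               paste(deparse(extra), collapse = ""), sep = "|")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- do.call(simulate_trial,
                                c(list(subject, jump_type, seed = seed), extra))
  }
  .fixtures[[key]]
}

# Classic planar double pendulum (two point masses on massless rods), angles
# measured from the DOWNWARD vertical: the standard textbook accelerations,
# used as an independent oracle for the chain equations of motion.
double_pendulum_acc <- function(phi1, phi2, w1, w2, m1, m2, L1, L2, g = 9.81) {
  d <- phi1 - phi2
  den <- 2 * m1 + m2 - m2 * cos(2 * d)
  a1 <- (-g * (2 * m1 + m2) * sin(phi1) - m2 * g * sin(phi1 - 2 * phi2) -
           2 * sin(d) * m2 * (w2^2 * L2 + w1^2 * L1 * cos(d))) / (L1 * den)
  a2 <- (2 * sin(d) * (w1^2 * L1 * (m1 + m2) + g * (m1 + m2) * cos(phi1) +
                         w2^2 * L2 * m2 * cos(d))) / (L2 * den)
  c(a1, a2)
}

# Chain model configured as that double pendulum (third segment massless).
double_pendulum_chain <- function(m1, m2, L1, L2) {
  m <- c(m1, m2, 0)
  I <- c(0, 0, 1e-9)
  r <- rbind(c(L1, 0, 0), c(L1, L2, 0), c(0, 0, 0))
  list(sp = NULL, m = m, I = I, r = r,
       S = t(r) %*% (m * r), mr = colSums(m * r),
       m_foot = 0, m_tot = sum(m), foot_com = c(0, 0), ankle_height = 0)
}
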