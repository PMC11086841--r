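# Shared fixtures: small conformations and potentials built in code.

# toy 4-atom conformation with low symmetry
toy_conf4 <- function() {
  conformation(c("A1", "A2", "A3", "A4"), 1:4, rep("C", 4),
               rbind(c(0, 0, 0), c(1.7, 0.2, -0.1), c(0.4, 1.9, 0.3),
                     c(-0.6, 0.5, 1.4)))
}

random_conformation <- function(n, seed, spread = 5) {
  set.seed(seed)
  conformation(paste0("A", seq_len(n)), seq_len(n), rep("C", n),
               matrix(stats::runif(3 * n, -spread, spread), ncol = 3))
}

random_rotation <- function(seed) {
  set.seed(seed)
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
}

# overdamped 1D configs used across sampling tests
od_config <- function(dt = 0.01, friction = 1, temperature = 300)
  langevin_config(temperature = temperature, friction = friction,
                  timestep = dt, mass = 1, scheme = "overdamped")

ud_config <- function(dt = 0.005, friction = 2, temperature = 300)
  langevin_config(temperature = temperature, friction = friction,
                  timestep = dt, mass = 1)
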