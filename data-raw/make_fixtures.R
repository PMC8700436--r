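# Builds the two synthetic benchmark-shaped fixture networks and writes them
# as BIF files under inst/extdata. Deterministic (no RNG); rerun to refresh.
suppressMessages(devtools::load_all(".", quiet = TRUE))

two <- c("True", "False")
cpt <- function(...) {
  v <- c(...)
  m <- matrix(v, ncol = 2, byrow = TRUE)
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  m
}

# 5-node network with the classic lung-cancer topology: two root risk factors
# pointing into the mid-graph class, two symptom children. Satisfies the
# ANB-recovery assumptions (every feature in the class Markov blanket, all
# blanket members adjacent to the class). CPTs are synthetic.
vars <- c("Pollution", "Smoker", "Cancer", "Xray", "Dyspnoea")
parents <- list(integer(0), integer(0), c(1L, 2L), 3L, 3L)
states <- setNames(list(c("low", "high"), two, two, c("positive", "negative"),
                        two), vars)
cpts <- list(
  cpt(0.85, 0.15),                 # Pollution: low, high
  cpt(0.35, 0.65),                 # Smoker: True, False
  # Cancer | Pollution, Smoker (configs: low/T, low/F, high/T, high/F)
  cpt(0.10, 0.90,
      0.02, 0.98,
      0.30, 0.70,
      0.08, 0.92),
  cpt(0.90, 0.10,                  # Xray | Cancer = True
      0.15, 0.85),                 #              = False
  cpt(0.70, 0.30,                  # Dyspnoea | Cancer = True
      0.25, 0.75))
g <- bn_structure(parents, names = vars, class_index = 3L)
cancer_like <- bn_model(g, cpts, states)
write_network(cancer_like, "inst/extdata/cancer_like_synthetic.bif")

# 8-node network with the classic chest-clinic topology; the class ("Either")
# has non-blanket ancestors (VisitAsia, Smoking) and a blanket member
# (Bronchitis, a co-parent of Dyspnoea) not adjacent to it, so the
# ANB-recovery assumptions are violated. The OR gate is made noisy to keep
# the distribution strictly positive. CPTs are synthetic.
vars <- c("VisitAsia", "Smoking", "Tuberculosis", "LungCancer", "Bronchitis",
          "Either", "Xray", "Dyspnoea")
parents <- list(integer(0), integer(0), 1L, 2L, 2L, c(3L, 4L), 6L, c(5L, 6L))
states <- setNames(rep(list(two), 8L), vars)
cpts <- list(
  cpt(0.05, 0.95),                 # VisitAsia
  cpt(0.50, 0.50),                 # Smoking
  cpt(0.20, 0.80,                  # Tuberculosis | VisitAsia = True
      0.02, 0.98),
  cpt(0.25, 0.75,                  # LungCancer | Smoking = True
      0.03, 0.97),
  cpt(0.60, 0.40,                  # Bronchitis | Smoking = True
      0.30, 0.70),
  # Either | Tuberculosis, LungCancer (noisy OR; configs T/T, T/F, F/T, F/F)
  cpt(0.98, 0.02,
      0.95, 0.05,
      0.95, 0.05,
      0.02, 0.98),
  cpt(0.95, 0.05,                  # Xray | Either = True
      0.10, 0.90),
  # Dyspnoea | Bronchitis, Either (configs T/T, T/F, F/T, F/F)
  cpt(0.95, 0.05,
      0.80, 0.20,
      0.70, 0.30,
      0.10, 0.90))
g <- bn_structure(parents, names = vars, class_index = 6L)
asia_like <- bn_model(g, cpts, states)
write_network(asia_like, "inst/extdata/asia_like_synthetic.bif")

# sanity: assumption checks
mb <- markov_blanket(cancer_like$structure, 3L)
stopifnot(setequal(mb, c(1, 2, 4, 5)))
mb2 <- markov_blanket(asia_like$structure, 6L)
cat("asia-like MB:", paste(asia_like$structure$names[mb2], collapse = ", "),
    "\n")  # excludes VisitAsia/Smoking; includes non-adjacent Bronchitis
cat("written\n")
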