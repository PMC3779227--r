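# shared fixtures built in code

STATES <- behaviour_states()

# a moderately mixing matrix with all entries well away from 0
mixing_matrix <- function() {
  matrix(c(0.40, 0.30, 0.15, 0.15,
           0.25, 0.40, 0.20, 0.15,
           0.20, 0.30, 0.35, 0.15,
           0.30, 0.25, 0.15, 0.30),
         4, 4, byrow = TRUE, dimnames = list(STATES, STATES))
}

# 4x4 transition counts with multinomial rows (row margins fixed; a scalar
# n_row is recycled, a length-4 vector sets each row's margin)
rcounts <- function(P, n_row = 200) {
  n_row <- rep_len(n_row, 4)
  m <- t(vapply(seq_len(4), function(i)
    if (n_row[i] > 0) drop(rmultinom(1, n_row[i], P[i, ])) else numeric(4),
    numeric(4)))
  dimnames(m) <- dimnames(P)
  class(m) <- c("transition_counts", class(m))
  m
}

# transition-pair data frame from a single simulated chain
sim_pairs <- function(P, n_transitions, init = NULL) {
  s <- simulate_chain(P, n_transitions, init)
  data.frame(state_from = s[-length(s)], state_to = s[-1],
             stringsAsFactors = FALSE)
}

# single-treatment design with one phase, for generator-level checks
one_group_design <- function(n_plots = 3, n_animals = 25, n_occ = 9) {
  occ <- paste0("t", seq_len(n_occ))
  experiment_design("T", n_plots, n_animals, occ,
                    setNames(rep("before", n_occ), occ))
}

one_group_params <- function(P, alpha = 3, resight = c(E = 1, S = 1, O = 1),
                             bounds = c(0.1, 4), seed = NULL) {
  k <- tp_key("T", "before")
  generator_params(setNames(list(P), k), setNames(alpha, k),
                   setNames(list(resight), k), step_bounds = bounds,
                   seed = seed)
}

# hand-built observation table from per-animal state sequences
table_from_sequences <- function(seqs, occ = NULL) {
  n_occ <- length(seqs[[1]])
  if (is.null(occ)) occ <- paste0("t", seq_len(n_occ))
  tb <- do.call(rbind, lapply(names(seqs), function(id)
    data.frame(animal_id = id, species = "abalone", plot = "p1",
               treatment = "T", phase = "before", occasion = occ,
               state = seqs[[id]], stringsAsFactors = FALSE)))
  attr(tb, "occasion_levels") <- occ
  tb
}
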