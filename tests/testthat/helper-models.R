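# Shared fixtures: the reference model (built once) and small hand-built
# models with closed-form behavior used as independent oracles.

ref_model <- build_reference_model()

# A -> B by mass action, both dynamic: A(t) = A0 e^{-kt}, B(t) = A0 (1 - e^{-kt}).
toy_ab <- function(k = 1, A0 = 1) {
  define_model(
    species = rbind(cd4_species("A", initial_level = A0),
                    cd4_species("B", initial_level = 0)),
    reactions = list(
      cd4_reaction("conv", substrates = c(A = 1), products = c(B = 1),
                   rate_law = ma_law("conv.k"))),
    parameters = c(conv.k = k))
}

# Boundary source A -> B (rate k*A), B -> 0 (rate d*B): B* = k*A/d.
toy_bd <- function(k = 2, d = 0.5, A = 1) {
  define_model(
    species = rbind(cd4_species("A", initial_level = A, is_boundary = TRUE),
                    cd4_species("B", initial_level = 0)),
    reactions = list(
      cd4_reaction("syn", substrates = c(A = 1), products = c(B = 1),
                   rate_law = ma_law("syn.k")),
      cd4_reaction("deg", substrates = c(B = 1),
                   rate_law = ma_law("deg.k"))),
    parameters = c(syn.k = k, deg.k = d))
}

# Two-step linear chain with boundary source: A -> X (k1), X -> 0 (k2).
# Steady state X* = k1*A/k2; steady flux J = k2*X* = k1*A.
toy_chain <- function(k1 = 1.3, k2 = 0.8, A = 1) {
  define_model(
    species = rbind(cd4_species("A", initial_level = A, is_boundary = TRUE),
                    cd4_species("X", initial_level = 0)),
    reactions = list(
      cd4_reaction("s1", substrates = c(A = 1), products = c(X = 1),
                   rate_law = ma_law("s1.k")),
      cd4_reaction("s2", substrates = c(X = 1),
                   rate_law = ma_law("s2.k"))),
    parameters = c(s1.k = k1, s2.k = k2))
}

# Random small mass-action model over n dynamic species (for the linearity
# property of the assembled right-hand side).
random_ma_model <- function(seed, n_spec = 4, n_rxn = 5) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_spec))
  species <- do.call(rbind, lapply(ids, function(id) {
    cd4_species(id, initial_level = runif(1, 0.2, 2))
  }))
  reactions <- lapply(seq_len(n_rxn), function(i) {
    from <- sample(ids, 1)
    to <- sample(setdiff(ids, from), 1)
    cd4_reaction(paste0("r", i),
                 substrates = stats::setNames(sample(1:2, 1), from),
                 products = stats::setNames(1, to),
                 rate_law = ma_law(paste0("r", i, ".k")))
  })
  pars <- stats::setNames(runif(n_rxn, 0.1, 2), paste0("r", seq_len(n_rxn), ".k"))
  define_model(species, reactions, pars)
}

# Keep one model with a sub-model per reaction: rhs(model) must equal the sum
# of the rhs of the single-reaction models (linearity in reaction rates).
rhs_by_reaction <- function(model, state) {
  Reduce(`+`, lapply(seq_along(model$reactions), function(j) {
    m_j <- model
    m_j$reactions <- model$reactions[j]
    assemble_rhs(m_j)(0, state)
  }))
}
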