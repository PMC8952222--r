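# Synthetic benchmark data: random species trees, orthologue families
# evolved under a BLOSUM-derived reversible substitution model with
# gamma-distributed site rates, and injected inter-protein site pairs whose
# substitutions co-occur on the same branches ("coevolving" scenario).
# Ground truth is recorded so detector sensitivity and specificity can be
# measured.

# BLOSUM62 background amino-acid frequencies (order AA20).
aa_frequencies <- function() {
  f <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
         E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
         M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
         Y = 0.032, V = 0.073)
  f / sum(f)
}

#' Reversible substitution rate matrix derived from a scoring matrix
#'
#' Exchangeabilities `2^(s_ij / 2)` (symmetric, from the log-odds scores)
#' combined with the background frequencies into a time-reversible rate
#' matrix, normalized to one expected substitution per site per unit time.
#' The eigendecomposition is returned so transition matrices can be built
#' per branch.
#'
#' @param matrix Scoring matrix name (default `"BLOSUM62"`).
#' @return List with `Q` (20 x 20 rate matrix), `freqs`, and the
#'   eigendecomposition (`values`, `U`, `Uinv`).
#' @export
substitution_model <- function(matrix = "BLOSUM62") {
  s <- substitution_matrix(matrix)
  f <- aa_frequencies()
  ex <- 2^(s / 2)
  Q <- sweep(ex, 2, f, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q <- Q / mu
  sym <- diag(sqrt(f)) %*% Q %*% diag(1 / sqrt(f))
  eg <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  list(Q = Q, freqs = f, values = eg$values,
       U = diag(1 / sqrt(f)) %*% eg$vectors,
       Uinv = t(eg$vectors) %*% diag(sqrt(f)))
}

# transition probability matrix for elapsed time t
transition_matrix <- function(model, t) {
  P <- model$U %*% (exp(model$values * t) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a random species tree
#'
#' Random bifurcating topology with exponentially distributed branch
#' lengths (mean `branch_mean` substitutions/site); deterministic under
#' `seed`.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param seed Integer seed.
#' @param branch_mean Mean branch length (default 0.05).
#' @return A rooted `ape::phylo` tree with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_taxa, seed = 1, branch_mean = 0.05) {
  if (n_taxa < 4L) stop_coev("coev_shape", "need at least 4 taxa")
  with_seed(derive_seed(seed, "tree", n_taxa), function() {
    tr <- ape::rtree(n_taxa, br = function(n) stats::rexp(n, 1 / branch_mean))
    tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
    tr
  })
}

#' Evolve a gap-free protein alignment along a tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies;
#' each site evolves under the continuous-time substitution model with its
#' own gamma-distributed rate (shape `rate_shape`, mean 1).
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths.
#' @param length Number of sites.
#' @param rate_shape Gamma shape for site rates (default 1).
#' @param seed Integer seed.
#' @param protein_id Protein id for the resulting alignment.
#' @param model A [substitution_model()] (rebuilt when `NULL`).
#' @return List with `msa` (gap-free `coev_msa`) and `rates`.
#' @export
evolve_protein <- function(tree, length, rate_shape = 1, seed = 1,
                           protein_id = "P1", model = NULL) {
  model <- model %||% substitution_model()
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  eo <- ape::reorder.phylo(tree, "cladewise")
  root <- nt + 1L
  with_seed(derive_seed(seed, "evolve", protein_id), function() {
    rates <- stats::rgamma(length, shape = rate_shape, rate = rate_shape)
    states <- matrix(NA_integer_, nn, length)
    states[root, ] <- sample.int(20L, length, replace = TRUE, prob = model$freqs)
    for (k in seq_len(nrow(eo$edge))) {
      a <- eo$edge[k, 1]; b <- eo$edge[k, 2]; t <- eo$edge.length[k]
      for (j in seq_len(length)) {
        if (rates[j] == 0) { states[b, j] <- states[a, j]; next }
        P <- transition_matrix(model, t * rates[j])
        states[b, j] <- sample.int(20L, 1L, prob = P[states[a, j], ])
      }
    }
    m <- matrix(AA20[states[seq_len(nt), , drop = FALSE]], nrow = nt)
    rownames(m) <- tree$tip.label
    list(msa = msa_from_matrix(protein_id, m), rates = rates)
  })
}

# Exact event-level (Gillespie) evolution of one site along one branch.
gillespie_branch <- function(model, x0, t, rate) {
  x <- x0; elapsed <- 0; events <- integer(0)
  repeat {
    total <- -model$Q[x, x] * rate
    if (total <= 0) break
    elapsed <- elapsed + stats::rexp(1, total)
    if (elapsed > t) break
    pr <- model$Q[x, ]; pr[x] <- 0
    x <- sample.int(20L, 1L, prob = pr)
    events <- c(events, x)
  }
  list(state = x, events = events)
}

# Simulate one coupled site pair along the tree. Site A evolves at `rate`;
# with probability `coupling` each substitution event at A forces a
# simultaneous substitution at B on the same branch (target residue drawn
# from residues scoring >= 0 against A's new residue, weighted by
# background frequency); B's own independent evolution runs at
# `(1 - coupling) * rate`.
simulate_coupled_pair <- function(tree, model, coupling, rate, blosum) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  eo <- ape::reorder.phylo(tree, "cladewise")
  root <- nt + 1L
  sa <- integer(nn); sb <- integer(nn)
  branches_a <- logical(nrow(eo$edge)); branches_b <- logical(nrow(eo$edge))
  sa[root] <- sample.int(20L, 1L, prob = model$freqs)
  sb[root] <- sample.int(20L, 1L, prob = model$freqs)
  for (k in seq_len(nrow(eo$edge))) {
    a <- eo$edge[k, 1]; b <- eo$edge[k, 2]; t <- eo$edge.length[k]
    ga <- gillespie_branch(model, sa[a], t, rate)
    sa[b] <- ga$state
    branches_a[k] <- length(ga$events) > 0L
    gb <- gillespie_branch(model, sb[a], t, (1 - coupling) * rate)
    xb <- gb$state
    nb_events <- length(gb$events)
    for (new_a in ga$events) {
      if (stats::runif(1) < coupling) {
        cand <- which(blosum[, new_a] >= 0)
        cand <- setdiff(cand, xb)
        if (length(cand)) {
          w <- model$freqs[cand]
          xb <- cand[sample.int(length(cand), 1L, prob = w)]
          nb_events <- nb_events + 1L
        }
      }
    }
    sb[b] <- xb
    branches_b[k] <- nb_events > 0L
  }
  list(col_a = AA20[sa[seq_len(nt)]], col_b = AA20[sb[seq_len(nt)]],
       branches_a = branches_a, branches_b = branches_b)
}

#' Inject coevolving site pairs into two alignments
#'
#' The listed site pairs are re-simulated jointly along the tree with the
#' given coupling strength and written into the alignments; all other
#' columns are untouched. Coupled sites evolve at `rate` (default 2, i.e.
#' twice the family mean: observable coevolution requires variable sites,
#' and at the default tree scale an average-rate site often carries fewer
#' than two substitution events).
#'
#' @param msa_a,msa_b Gap-free `coev_msa` objects over the tree's species.
#' @param tree Rooted `ape::phylo` species tree.
#' @param pairs Data.frame with columns `site_a`, `site_b` (1-based,
#'   non-overlapping within each protein).
#' @param coupling Coupling probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param rate Evolutionary rate of the coupled sites (default 2).
#' @param matrix Scoring matrix used to pick compatible target residues.
#' @return List with modified `msa_a`, `msa_b`, and `truth`: `pairs` with
#'   `coupling` plus per-pair substitution branch sets (`branches_a`,
#'   `branches_b`, logical vectors over cladewise edges).
#' @export
inject_coevolution <- function(msa_a, msa_b, tree, pairs, coupling, seed = 1,
                               rate = 2, matrix = "BLOSUM62") {
  if (coupling < 0 || coupling > 1) stop_coev("coev_config", "coupling must be in [0, 1]")
  if (anyDuplicated(pairs$site_a) || anyDuplicated(pairs$site_b))
    stop_coev("coev_config", "overlapping coupled sites")
  if (any(pairs$site_a > msa_length(msa_a)) || any(pairs$site_b > msa_length(msa_b)))
    stop_coev("coev_shape", "coupled site outside protein length")
  model <- substitution_model(matrix)
  blosum <- substitution_matrix(matrix)
  sims <- with_seed(
    derive_seed(seed, "inject", msa_a$protein_id, msa_b$protein_id),
    function() lapply(seq_len(nrow(pairs)), function(k)
      simulate_coupled_pair(tree, model, coupling, rate, blosum)))
  branches_a <- lapply(sims, `[[`, "branches_a")
  branches_b <- lapply(sims, `[[`, "branches_b")
  for (k in seq_len(nrow(pairs))) {
    msa_a$seq[, pairs$site_a[k]] <-
      sims[[k]]$col_a[match(msa_a$species, tree$tip.label)]
    msa_b$seq[, pairs$site_b[k]] <-
      sims[[k]]$col_b[match(msa_b$species, tree$tip.label)]
  }
  truth <- pairs
  truth$coupling <- coupling
  list(msa_a = msa_a, msa_b = msa_b,
       truth = truth, branches_a = branches_a, branches_b = branches_b)
}

#' Simulate a complete benchmark dataset in memory
#'
#' Species tree, per-protein orthologue alignments with gamma site-rate
#' heterogeneity and, for the coevolving scenario, `n_coupled` injected
#' site pairs between the first two proteins.
#'
#' @param scenario `"independent"` or `"coevolving"`.
#' @param n_proteins Number of proteins (default 10).
#' @param n_taxa Number of taxa (default 30).
#' @param length Columns per protein (default 200).
#' @param n_coupled Injected site pairs (default 10; coevolving only).
#' @param coupling Coupling strength (default 1).
#' @param seed Integer seed.
#' @param rate_shape Gamma shape for site rates (default 1).
#' @param coupled_rate Rate of coupled sites (default 2).
#' @param gap_fraction Fraction of alignment cells gapped out in random
#'   blocks (default 0: gap-free).
#' @return List of class `coev_simulation`: `tree`, `msas` (named list),
#'   `truth` (data.frame protein_a, site_a, protein_b, site_b, coupling),
#'   `scenario`, `seed`.
#' @export
simulate_dataset <- function(scenario = c("independent", "coevolving"),
                             n_proteins = 10, n_taxa = 30, length = 200,
                             n_coupled = 10, coupling = 1, seed = 1,
                             rate_shape = 1, coupled_rate = 2,
                             gap_fraction = 0) {
  scenario <- match.arg(scenario)
  if (n_proteins < 2L) stop_coev("coev_shape", "need >= 2 proteins")
  tree <- simulate_species_tree(n_taxa, seed = seed)
  model <- substitution_model()
  ids <- sprintf("P%02d", seq_len(n_proteins))
  msas <- lapply(ids, function(id)
    evolve_protein(tree, length, rate_shape = rate_shape,
                   seed = seed, protein_id = id, model = model)$msa)
  names(msas) <- ids
  truth <- data.frame(protein_a = character(), site_a = integer(),
                      protein_b = character(), site_b = integer(),
                      coupling = numeric(), stringsAsFactors = FALSE)
  if (scenario == "coevolving" && n_coupled > 0) {
    sites <- with_seed(derive_seed(seed, "sites"), function() {
      data.frame(site_a = sample.int(length, n_coupled),
                 site_b = sample.int(length, n_coupled))
    })
    inj <- inject_coevolution(msas[[1]], msas[[2]], tree, sites, coupling,
                              seed = seed, rate = coupled_rate)
    msas[[1]] <- inj$msa_a; msas[[2]] <- inj$msa_b
    truth <- data.frame(protein_a = ids[1], site_a = sites$site_a,
                        protein_b = ids[2], site_b = sites$site_b,
                        coupling = coupling, stringsAsFactors = FALSE)
  }
  if (gap_fraction > 0) {
    msas <- with_seed(derive_seed(seed, "gaps"), function() {
      lapply(msas, function(m) {
        ncell <- nrow(m$seq) * ncol(m$seq)
        n_blocks <- max(1L, round(gap_fraction * ncell / 10))
        for (b in seq_len(n_blocks)) {
          r <- sample.int(nrow(m$seq), 1L)
          start <- sample.int(ncol(m$seq), 1L)
          end <- min(ncol(m$seq), start + 9L)
          m$seq[r, start:end] <- "-"
        }
        m
      })
    })
  }
  structure(list(tree = tree, msas = msas, truth = truth,
                 scenario = scenario, seed = seed),
            class = "coev_simulation")
}

#' Write a simulated dataset in the pipeline's input layout
#'
#' Writes per-protein FASTA alignments (`msa/<id>.fasta`), `species.txt`,
#' `proteins.txt`, the species tree (`tree.nwk`) and the ground-truth
#' table (`truth.tsv`); byte-identical for a given seed.
#'
#' @inheritParams simulate_dataset
#' @param out_dir Output directory (created).
#' @return The `coev_simulation`, invisibly, with `$dir` set.
#' @export
make_dataset <- function(out_dir, scenario = c("independent", "coevolving"),
                         n_proteins = 10, n_taxa = 30, length = 200,
                         n_coupled = 10, coupling = 1, seed = 1,
                         rate_shape = 1, coupled_rate = 2, gap_fraction = 0) {
  sim <- simulate_dataset(scenario, n_proteins, n_taxa, length, n_coupled,
                          coupling, seed, rate_shape, coupled_rate, gap_fraction)
  dir.create(file.path(out_dir, "msa"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(sim$msas))
    write_msa(sim$msas[[id]], file.path(out_dir, "msa", paste0(id, ".fasta")))
  writeLines(sim$tree$tip.label, file.path(out_dir, "species.txt"))
  writeLines(names(sim$msas), file.path(out_dir, "proteins.txt"))
  write_newick(sim$tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sim$dir <- out_dir
  invisible(sim)
}
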