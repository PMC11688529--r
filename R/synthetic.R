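# Synthetic-study generator: Yule trees, Markov regime histories, COX-like
# alignments with ground-truthed state codons, and multi-regime OU traits.
# One call produces every input the pipeline consumes plus a truth ledger,
# so recovery can be scored without any external data.

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree conditioned on the number of extant tips (via
#' [ape::rphylo()] with zero extinction), rescaled to the configured height
#' and relabelled `sp0001...`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param height Height the tree is scaled to (relative time units);
#'   `NULL` keeps the natural birth-process time scale.
#' @param seed Optional seed.
#' @return A `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, height = 1, seed = NULL) {
  stopifnot(n_tips >= 2)
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    if (!is.null(height))
      tr$edge.length <- tr$edge.length / tree_height(tr) * height
    tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
    tr
  })
}

#' Simulate a COX-like alignment with ground-truthed state codons
#'
#' Neutral evolution under the substitution model at every site except the
#' two mapped codons, which are overwritten per tip to encode that tip's
#' regime as an amino-acid pair -- Lys+Ser (`AAR` + `TCN`) for LS, Cys+Cys
#' (`TGY` + `TGY`) for CC, Cys+Ser (`TGY` + `TCN`) for CS -- with the
#' synonymous codon chosen at random, so silent variation does not betray
#' the regime. By construction [classify_cox_state()] on any tip recovers
#' the generated regime.
#'
#' @param tree A `phylo` object.
#' @param node_states Character states per node (ape order), e.g. from
#'   [simulate_regime_history()].
#' @param model A [subst_model()] for the neutral sites.
#' @param L Alignment length (>= 6).
#' @param site_map List of two length-3 column vectors for the state codons.
#' @param rescale Branch-length multiplier into substitutions/site.
#' @param seed Optional seed.
#' @return Character matrix species x site with attribute `site_map`.
#' @export
simulate_alignment_with_cox_site <- function(tree, node_states,
                                             model = subst_model("JC", gamma = TRUE,
                                                                 shape = 0.5),
                                             L = 237,
                                             site_map = list(58:60, 61:63),
                                             rescale = 0.3, seed = NULL) {
  stopifnot(L >= 6, is.list(site_map), length(site_map) == 2L)
  cols <- unlist(site_map)
  if (length(unique(cols)) != 6L)
    stop("site_map codons overlap", call. = FALSE)
  if (min(cols) < 1 || max(cols) > L) stop("site_map outside [1, L]", call. = FALSE)
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    n_all <- n_tip + tree$Nnode
    eig <- subst_eigen(model)
    rates <- if (model$gamma) discrete_gamma_rates(model$shape, model$k) else 1
    site_rate <- sample(rates, L, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    seqs <- matrix(NA_integer_, n_all, L)
    root <- n_tip + 1L
    seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$base_freq)
    for (e in preorder_edges(tree)) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      t_e <- tree$edge.length[e] * rescale
      for (r in unique(site_rate)) {
        P <- transition_prob(eig, r * t_e)
        sel <- which(site_rate == r)
        seqs[chl, sel] <- vapply(seqs[par, sel], function(b)
          sample.int(4L, 1L, prob = P[b, ]), integer(1))
      }
    }
    m <- matrix(bases[seqs[seq_len(n_tip), ]], n_tip, L,
                dimnames = list(tree$tip.label, NULL))
    ser <- c("TCT", "TCC", "TCA", "TCG")
    cys <- c("TGT", "TGC")
    lys <- c("AAA", "AAG")
    for (i in seq_len(n_tip)) {
      st <- node_states[i]
      codons <- switch(st,
                       LS = c(sample(lys, 1), sample(ser, 1)),
                       CC = c(sample(cys, 1), sample(cys, 1)),
                       CS = c(sample(cys, 1), sample(ser, 1)),
                       stop("unknown regime state: ", st))
      m[i, site_map[[1]]] <- strsplit(codons[1], "")[[1]]
      m[i, site_map[[2]]] <- strsplit(codons[2], "")[[1]]
    }
    structure(m, site_map = site_map)
  })
}

#' Configure a synthetic study
#'
#' Defaults emulate the empirical study conditions: a tree of comparable
#' size scaled to unit height, a sequential LS -> CC -> CS regime history
#' with a rate giving a handful of transitions, a 237-site JC+Gamma
#' alignment carrying the state codons, and log10-scale traits generated
#' under a multi-regime OU model whose genome-size optima sit at
#' log10(597), log10(210) and log10(51.09) Mbp (chromosome-size optima at
#' log10(55.41), log10(12.21), log10(2.18) Mbp).
#'
#' @param n_tips Tips in the Yule tree.
#' @param birth_rate Yule speciation rate.
#' @param height Tree height (relative time).
#' @param q Regime transition rate per allowed move.
#' @param reversal Allow the CC -> LS reversal.
#' @param L Alignment length.
#' @param site_map Columns of the two state codons.
#' @param subst Substitution model for neutral sites.
#' @param seq_rescale Tree-to-substitutions branch multiplier.
#' @param trait_model Generating trait model name (default `"OUMA"`).
#' @param theta_genome,theta_chrom Generating optima (log10 Mbp) per regime.
#' @param alpha Generating attraction per regime (1/time).
#' @param sigma2 Generating diffusion variance (log10-trait^2/time).
#' @param seq_coverage Fraction of tips with a sequence in the bundle's
#'   alignment (the rest rely on taxonomic imputation, as in real data).
#' @param regime_frac_bands Named list of `c(lo, hi)` tip-fraction bands
#'   per regime; histories are redrawn (with derived seeds) until the tip
#'   composition falls inside every band. The defaults mirror the
#'   empirical composition: a deep CC gain spanning roughly half the
#'   species, a substantial LS share, and a smaller but non-trivial CS
#'   clade.
#' @return A `synthetic_study_config` list.
#' @export
synthetic_study_config <- function(n_tips = 120, birth_rate = 1, height = 1,
                                   q = 0.35, reversal = FALSE,
                                   L = 237, site_map = list(58:60, 61:63),
                                   subst = subst_model("JC", gamma = TRUE, shape = 0.5),
                                   seq_rescale = 0.3,
                                   trait_model = "OUMA",
                                   theta_genome = log10(c(LS = 597, CC = 210, CS = 51.09)),
                                   theta_chrom = log10(c(LS = 55.41, CC = 12.21, CS = 2.18)),
                                   alpha = c(LS = 1.5, CC = 3, CS = 6),
                                   sigma2 = 0.135,
                                   seq_coverage = 0.6,
                                   regime_frac_bands = list(LS = c(0.2, 0.7),
                                                            CC = c(0.2, 0.7),
                                                            CS = c(0.05, 0.5))) {
  stopifnot(n_tips >= 4, L >= 6, q >= 0, seq_coverage > 0, seq_coverage <= 1)
  structure(as.list(environment()), class = "synthetic_study_config")
}

#' Build a complete synthetic study bundle
#'
#' One seeded call generates every pipeline input -- tree, regime history,
#' alignment (for a subset of tips, emulating incomplete sequencing),
#' trait table, state table, taxonomy table -- plus a truth ledger holding
#' the generating node states, painting and parameters for recovery scoring.
#'
#' @param config A [synthetic_study_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `synthetic_study` with elements `tree`,
#'   `alignment`, `traits`, `states`, `taxonomy`, `truth`, `config`, `seed`.
#' @export
build_synthetic_study <- function(config = synthetic_study_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_study_config"))
  seeds <- derive_seeds(seed, 6L)
  tree <- simulate_yule_tree(config$n_tips, config$birth_rate, config$height,
                             seed = seeds[1])
  alphabet <- c("LS", "CC", "CS")

  hist_seeds <- derive_seeds(seeds[2], 400L)
  history <- NULL
  bands <- config$regime_frac_bands
  for (s in hist_seeds) {
    cand <- simulate_regime_history(tree, config$q, alphabet = alphabet,
                                    reversal = config$reversal, seed = s)
    tip_frac <- table(factor(cand$node_states[seq_len(config$n_tips)],
                             levels = alphabet)) / config$n_tips
    in_band <- vapply(alphabet, function(a)
      tip_frac[[a]] >= bands[[a]][1] && tip_frac[[a]] <= bands[[a]][2],
      logical(1))
    if (all(in_band)) {
      history <- cand
      break
    }
  }
  if (is.null(history))
    stop("no regime history inside the composition bands in 400 draws; ",
         "widen regime_frac_bands or raise q/n_tips", call. = FALSE)

  alignment <- simulate_alignment_with_cox_site(
    tree, history$node_states, model = config$subst, L = config$L,
    site_map = config$site_map, rescale = config$seq_rescale, seed = seeds[3])

  spec <- ou_model(config$trait_model)
  par_genome <- ou_params(spec, alphabet, theta = config$theta_genome,
                          alpha = config$alpha, sigma2 = config$sigma2)
  par_chrom <- ou_params(spec, alphabet, theta = config$theta_chrom,
                         alpha = config$alpha, sigma2 = config$sigma2)
  g <- simulate_traits(tree, history$painting, par_genome, seed = seeds[4])
  c_ <- simulate_traits(tree, history$painting, par_chrom, seed = seeds[5])
  genome_mbp <- 10^g$trait
  chrom_mbp <- 10^c_$trait
  chrom_n <- pmax(1L, round(genome_mbp / chrom_mbp))
  traits <- tibble(species = g$species,
                   genome_size_1C_Mbp = genome_mbp,
                   chromosome_number = chrom_n,
                   mean_chromosome_size_Mbp = genome_mbp / chrom_n)

  tip_states <- history$node_states[seq_len(config$n_tips)]
  n_seq <- max(2L, round(config$seq_coverage * config$n_tips))
  sequenced <- with_seed(seeds[6], sort(sample.int(config$n_tips, n_seq)))
  states <- tibble(species = tree$tip.label,
                   cox_state = ifelse(seq_len(config$n_tips) %in% sequenced,
                                      tip_states, NA_character_))
  taxonomy <- tibble(species = tree$tip.label,
                     genus = c(LS = "Pinguicula", CC = "Utricularia",
                               CS = "Genlisea")[tip_states],
                     section = ifelse(tip_states == "CS", "Genlisea", NA_character_))

  structure(list(
    tree = tree,
    alignment = alignment[sequenced, , drop = FALSE],
    traits = traits, states = states, taxonomy = taxonomy,
    truth = list(node_states = history$node_states,
                 painting = history$painting,
                 trait_model = config$trait_model,
                 theta_genome = config$theta_genome,
                 theta_chrom = config$theta_chrom,
                 alpha = config$alpha, sigma2 = config$sigma2,
                 log_traits_genome = setNames(g$trait, g$species),
                 log_traits_chrom = setNames(c_$trait, c_$species),
                 sequenced = tree$tip.label[sequenced]),
    config = config, seed = seed), class = "synthetic_study")
}

#' Write a synthetic study bundle to disk in the pipeline's file formats
#'
#' Newick tree, FASTA alignment, CSV trait/state/taxonomy tables and a JSON
#' truth ledger.
#'
#' @param study A [build_synthetic_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  write_fasta(study$alignment, file.path(dir, "alignment.fasta"))
  utils::write.csv(study$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(study$states, file.path(dir, "states.csv"), row.names = FALSE)
  utils::write.csv(study$taxonomy, file.path(dir, "taxonomy.csv"), row.names = FALSE)
  truth <- study$truth
  truth$painting <- as.data.frame(truth$painting)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = study$seed,
                            site_map = study$config$site_map,
                            n_tips = study$config$n_tips),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
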