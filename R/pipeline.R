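# Study orchestration: data reconciliation with an auditable species-drop
# manifest, the ancestral-sequence route and the taxonomic-imputation route
# to COX states, per-trait PGLS + seven-model OU comparison + bootstrap.

#' Impute COX states from phylogenetic affiliation
#'
#' Species without a sequence-determined state receive the state uniform in
#' their group: genus *Pinguicula* -> LS, genus *Utricularia* -> CC, and
#' genus *Genlisea* by section (*Tayloria* -> LS, *Recurvatae* -> CC,
#' *Genlisea* -> CS). Every record is flagged `"sequenced"` or `"imputed"`;
#' species whose group is unknown stay `NA` and are listed in the
#' `unresolved` attribute.
#'
#' @param states Data frame with `species` and `cox_state` (NA = unknown).
#' @param taxonomy Data frame with `species`, `genus` and (for *Genlisea*)
#'   `section`.
#' @return Tibble with `species`, `cox_state`, `source`.
#' @export
impute_states_by_affiliation <- function(states, taxonomy) {
  st <- as_tibble(states)
  stopifnot(all(c("species", "cox_state") %in% names(st)))
  tx <- as_tibble(taxonomy)
  stopifnot(all(c("species", "genus") %in% names(tx)))
  if (!"section" %in% names(tx)) tx$section <- NA_character_
  tx$key <- species_key(tx$species)
  st$key <- species_key(st$species)
  merged <- dplyr::left_join(st, tx[, c("key", "genus", "section")], by = "key")
  rule <- function(genus, section) {
    dplyr::case_when(
      genus == "Pinguicula" ~ "LS",
      genus == "Utricularia" ~ "CC",
      genus == "Genlisea" & section == "Tayloria" ~ "LS",
      genus == "Genlisea" & section == "Recurvatae" ~ "CC",
      genus == "Genlisea" & section == "Genlisea" ~ "CS",
      TRUE ~ NA_character_)
  }
  imputed <- rule(merged$genus, merged$section)
  out <- tibble(
    species = merged$species,
    cox_state = dplyr::coalesce(merged$cox_state, imputed),
    source = dplyr::case_when(
      !is.na(merged$cox_state) ~ "sequenced",
      !is.na(imputed) ~ "imputed",
      TRUE ~ NA_character_))
  unresolved <- out$species[is.na(out$cox_state)]
  if (length(unresolved))
    warning("species with unknown group left unassigned: ",
            paste(unresolved, collapse = ", "))
  structure(out, unresolved = unresolved)
}

# Internal node states on `target_tree` carried over from an ancestral
# reconstruction on `asr_tree` (possibly a subset of species): each internal
# node maps to the MRCA of its reconstructed descendants; nodes without two
# reconstructed descendants inherit their parent's state.
map_internal_states <- function(target_tree, tip_states, asr_tree, asr_states) {
  n_tip <- ape::Ntip(target_tree)
  n_all <- n_tip + target_tree$Nnode
  states <- character(n_all)
  states[seq_len(n_tip)] <- tip_states
  asr_labs <- species_key(asr_tree$tip.label)
  desc <- desc_tips(target_tree)
  for (v in seq.int(n_tip + 1L, n_all)) {
    tips_v <- species_key(target_tree$tip.label[desc[[v]]])
    on_asr <- intersect(tips_v, asr_labs)
    if (length(on_asr) >= 2L) {
      m <- ape::getMRCA(asr_tree, match(on_asr, asr_labs))
      states[v] <- asr_states[m]
    } else if (length(on_asr) == 1L) {
      states[v] <- asr_states[match(on_asr, asr_labs)]
    } else states[v] <- NA_character_
  }
  # fill unmapped nodes from their parent (preorder), root defaults to LS
  root <- n_tip + 1L
  if (is.na(states[root])) states[root] <- "LS"
  for (e in preorder_edges(target_tree)) {
    chl <- target_tree$edge[e, 2]
    if (chl > n_tip && is.na(states[chl]))
      states[chl] <- states[target_tree$edge[e, 1]]
  }
  states
}

# List of descendant tip indices per node.
desc_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  out <- vector("list", n_all)
  for (i in seq_len(n_tip)) out[[i]] <- i
  for (e in rev(preorder_edges(tree))) {
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    out[[par]] <- c(out[[par]], out[[chl]])
  }
  out
}

# Internal states by ML Mk reconstruction of the discrete regime (ape::ace,
# equal-rates model), falling back to descendant majority if ace fails.
internal_states_mk <- function(tree, tip_states, alphabet = c("LS", "CC", "CS")) {
  n_tip <- ape::Ntip(tree)
  states <- character(n_tip + tree$Nnode)
  states[seq_len(n_tip)] <- tip_states
  present <- intersect(alphabet, unique(tip_states))
  if (length(present) == 1L) {
    states[] <- present
    states[seq_len(n_tip)] <- tip_states
    return(states)
  }
  anc <- tryCatch({
    a <- ape::ace(factor(tip_states, levels = present), tree,
                  type = "discrete", model = "ER")
    colnames(a$lik.anc)[max.col(a$lik.anc, ties.method = "first")]
  }, error = function(e) NULL)
  if (is.null(anc)) {
    dt <- desc_tips(tree)
    anc <- vapply(seq.int(n_tip + 1L, n_tip + tree$Nnode), function(v) {
      tab <- table(factor(tip_states[dt[[v]]], levels = alphabet))
      names(tab)[which.max(tab)]
    }, character(1))
  }
  states[(n_tip + 1L):(n_tip + tree$Nnode)] <- anc
  states
}

#' Run the full comparative study
#'
#' Orchestrates the pipeline on one set of inputs: reconcile species across
#' tree, trait table and COX-state sources (every drop is recorded in a
#' manifest); reconstruct ancestral sequences and classify node states when
#' an alignment is supplied (substitution model chosen by BIC); paint
#' regimes; and per trait run the PGLS error-model selection and
#' regression, the seven-model OU comparison, and (optionally) the
#' parametric bootstrap with pairwise regime tests. When both a sequence
#' source and a taxonomy are available the analyses are run twice -- once
#' restricted to sequence-determined states, once with taxonomically
#' imputed states -- mirroring the robustness design of the original
#' analysis.
#'
#' @param tree Ultrametric `phylo`, or a `synthetic_study` bundle (then the
#'   other data arguments default to the bundle's components).
#' @param traits Data frame with `species` and the trait columns.
#' @param alignment Optional character matrix of COX sequences (ASR route).
#' @param states Optional data frame `species`/`cox_state` (direct route).
#' @param taxonomy Optional data frame for [impute_states_by_affiliation()].
#' @param site_map Codon columns for [classify_cox_state()] (required with
#'   `alignment`).
#' @param trait_cols Named character vector of trait columns to analyse
#'   (values are column names; names label the results).
#' @param variant `"both"`, `"imputed"` or `"sequenced-only"`.
#' @param n_boot Bootstrap replicates (0 skips the bootstrap).
#' @param n_starts Optimizer starts for the OU fits.
#' @param criterion `"AICc"` or `"AIC"` for all weight computations.
#' @param models OU model set to compare.
#' @param seed Master seed.
#' @return A `study_report` list: `manifest`, `asr`, `variants` (per
#'   variant, per trait: `pgls_selection`, `pgls`, `ou_comparison`,
#'   `theta`, `bootstrap_tests`), `provenance`.
#' @export
run_study <- function(tree, traits = NULL, alignment = NULL, states = NULL,
                      taxonomy = NULL, site_map = NULL,
                      trait_cols = c(genome = "genome_size_1C_Mbp",
                                     chromosome = "mean_chromosome_size_Mbp"),
                      variant = c("both", "imputed", "sequenced-only"),
                      n_boot = 0, n_starts = 8,
                      criterion = c("AICc", "AIC"),
                      models = c("BM1", "BMS", "OU1", "OUM", "OUMV", "OUMA",
                                 "OUMVA"),
                      seed = 1) {
  variant <- match.arg(variant)
  criterion <- match.arg(criterion)
  if (inherits(tree, "synthetic_study")) {
    bundle <- tree
    tree <- bundle$tree
    traits <- traits %||% bundle$traits
    alignment <- alignment %||% bundle$alignment
    states <- states %||% bundle$states
    taxonomy <- taxonomy %||% bundle$taxonomy
    site_map <- site_map %||% bundle$config$site_map
  }
  if (is.null(traits)) stop("trait table is required", call. = FALSE)
  if (!isTRUE(as.logical(check_ultrametric(tree))))
    stop("tree is not ultrametric; trait analyses refuse non-ultrametric trees",
         call. = FALSE)
  traits <- as_tibble(traits)
  if (!"species" %in% names(traits))
    stop("trait table needs a `species` column", call. = FALSE)
  missing_cols <- setdiff(unname(trait_cols), names(traits))
  if (length(missing_cols))
    stop("trait column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  labs <- species_key(tree$tip.label)

  # --- COX states: sequence route -------------------------------------
  asr_out <- NULL
  seq_states <- NULL
  if (!is.null(alignment)) {
    if (is.null(site_map)) stop("site_map is required with an alignment", call. = FALSE)
    m <- as_alignment_matrix(alignment)
    tip_cls <- classify_cox_tips(m, site_map)
    on_tree <- species_key(tip_cls$species) %in% labs
    asr_tree <- prune_to(tree, tip_cls$species[on_tree])
    bic <- select_model_bic(asr_tree, m[on_tree, , drop = FALSE])
    best_model <- bic$fit[[1]]
    asr <- marginal_asr(asr_tree, m[on_tree, , drop = FALSE], best_model$model,
                        rescale = best_model$rescale)
    n_tip_asr <- ape::Ntip(asr_tree)
    internal_nodes <- seq.int(n_tip_asr + 1L, n_tip_asr + asr_tree$Nnode)
    internal_cls <- vapply(internal_nodes, function(v)
      as.character(suppressWarnings(classify_cox_state(asr, site_map, node = v))),
      character(1))
    # nodes whose MAP codons translate outside {LS, CC, CS} carry no regime
    # information; they inherit a neighbour's state during tree mapping
    internal_cls[internal_cls == "other"] <- NA_character_
    asr_tip_states <- classify_cox_tips(m[on_tree, , drop = FALSE], site_map)$cox_state
    asr_tip_states[asr_tip_states == "other"] <- NA_character_
    asr_states <- c(asr_tip_states[match(species_key(asr_tree$tip.label),
                                         species_key(tip_cls$species[on_tree]))],
                    internal_cls)
    asr_out <- list(model_table = dplyr::select(bic, -"fit"),
                    model = best_model$model, rescale = best_model$rescale,
                    tree = asr_tree, reconstruction = asr,
                    node_states = asr_states,
                    root_state = asr_states[n_tip_asr + 1L])
    seq_states <- tibble(species = tip_cls$species, cox_state = tip_cls$cox_state,
                         source = "sequenced")
    seq_states$cox_state[seq_states$cox_state == "other"] <- NA_character_
  }

  # --- merge state sources --------------------------------------------
  base_states <- if (!is.null(states)) {
    st <- as_tibble(states)
    st$source <- ifelse(is.na(st$cox_state), NA_character_, "sequenced")
    st[, c("species", "cox_state", "source")]
  } else NULL
  if (!is.null(seq_states)) {
    if (is.null(base_states)) base_states <- seq_states
    else {
      key_new <- setdiff(species_key(seq_states$species),
                         species_key(base_states$species))
      idx <- match(species_key(base_states$species), species_key(seq_states$species))
      fill <- !is.na(idx) & is.na(base_states$cox_state)
      base_states$cox_state[fill] <- seq_states$cox_state[idx[fill]]
      base_states$source[fill] <- "sequenced"
      base_states <- dplyr::bind_rows(
        base_states, seq_states[species_key(seq_states$species) %in% key_new, ])
    }
  }
  if (is.null(base_states))
    stop("supply an alignment or a state table", call. = FALSE)

  variants <- list()
  want_seq <- variant %in% c("both", "sequenced-only")
  want_imp <- variant %in% c("both", "imputed") && !is.null(taxonomy)
  if (variant == "imputed" && is.null(taxonomy))
    stop("imputed variant requires a taxonomy table", call. = FALSE)
  if (want_seq)
    variants[["sequenced_only"]] <- base_states[!is.na(base_states$cox_state) &
                                                  base_states$source == "sequenced", ]
  if (want_imp)
    variants[["imputed"]] <- suppressWarnings(
      impute_states_by_affiliation(base_states, taxonomy))

  analyse_variant <- function(state_tbl, vseed) {
    per_trait <- list()
    manifest <- list()
    for (tn in names(trait_cols)) {
      col <- trait_cols[[tn]]
      man <- tibble(species = traits$species,
                    on_tree = species_key(traits$species) %in% labs,
                    has_trait = !is.na(traits[[col]]))
      st_idx <- match(species_key(man$species), species_key(state_tbl$species))
      man$has_state <- !is.na(st_idx) & !is.na(state_tbl$cox_state[st_idx])
      man$state <- ifelse(man$has_state, state_tbl$cox_state[st_idx], NA_character_)
      man$analysed <- man$on_tree & man$has_trait & man$has_state
      man$drop_reason <- dplyr::case_when(
        man$analysed ~ NA_character_,
        !man$on_tree ~ "not on tree",
        !man$has_trait ~ "missing trait",
        TRUE ~ "missing COX state")
      manifest[[tn]] <- man
      if (sum(man$analysed) < 10L) {
        per_trait[[tn]] <- list(error = "fewer than 10 analysable species")
        next
      }
      dat <- tibble(species = man$species[man$analysed],
                    value = log10(traits[[col]][man$analysed]),
                    cox_state = man$state[man$analysed])
      tr <- prune_to(tree, dat$species)
      tip_states <- dat$cox_state[match(species_key(tr$tip.label),
                                        species_key(dat$species))]
      if (length(unique(tip_states)) < 2L) {
        per_trait[[tn]] <- list(error = "single COX state among analysed species; group contrast undefined")
        next
      }
      node_states <- if (!is.null(asr_out)) {
        map_internal_states(tr, tip_states, asr_out$tree, asr_out$node_states)
      } else internal_states_mk(tr, tip_states)
      alphabet_here <- intersect(c("LS", "CC", "CS"),
                                 unique(node_states))
      painting <- paint_regimes(tr, node_states, alphabet = alphabet_here)

      sel <- select_error_model(dat, tr, "value", "cox_state",
                                criterion = criterion)
      best_pgls <- sel$fit[[1]]
      second_pgls <- if (nrow(sel) >= 2L && !inherits(sel$fit[[2]], "error"))
        sel$fit[[2]] else NULL

      comp <- suppressWarnings(
        fit_ou_models(tr, painting, setNames(dat$value, dat$species),
                      models = models, criterion = criterion,
                      n_starts = n_starts, seed = vseed))
      theta_models <- comp$model[vapply(comp$fit, function(f)
        !is.null(f$params$theta) && length(f$params$theta) > 1L, logical(1))]
      boot <- NULL; boot_tests <- NULL
      if (n_boot > 0 && length(theta_models)) {
        bfit <- comp$fit[[match(theta_models[1], comp$model)]]
        boot <- suppressWarnings(
          parametric_bootstrap_theta(bfit, n_replicates = n_boot, seed = vseed))
        boot_tests <- suppressWarnings(compare_regime_optima(boot))
      }
      per_trait[[tn]] <- list(
        n = nrow(dat),
        pgls_selection = dplyr::select(sel, -"fit"),
        pgls = best_pgls, pgls_second = second_pgls,
        ou_comparison = comp,
        best_ou = comp$model[1],
        theta = if (!is.null(comp$fit[[1]]$params$theta))
          tibble(regime = names(comp$fit[[1]]$params$theta),
                 theta_log10 = unname(comp$fit[[1]]$params$theta),
                 theta_mbp = 10^unname(comp$fit[[1]]$params$theta)) else NULL,
        bootstrap = boot, bootstrap_tests = boot_tests,
        painting = painting)
    }
    list(traits = per_trait, manifest = manifest)
  }

  vseeds <- derive_seeds(seed, length(variants))
  results <- list()
  for (i in seq_along(variants)) {
    results[[names(variants)[i]]] <- analyse_variant(variants[[i]], vseeds[i])
  }

  structure(list(
    manifest = lapply(results, function(r) r$manifest),
    asr = asr_out,
    states = variants,
    variants = lapply(results, function(r) r$traits),
    provenance = list(seed = seed, criterion = criterion,
                      n_boot = n_boot, n_starts = n_starts,
                      package_version = as.character(utils::packageVersion("ouregime")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> variants:", paste(names(x$variants), collapse = ", "), "\n")
  for (v in names(x$variants)) {
    for (tn in names(x$variants[[v]])) {
      res <- x$variants[[v]][[tn]]
      if (!is.null(res$error)) {
        cat(sprintf("  %s / %s: %s\n", v, tn, res$error))
        next
      }
      cat(sprintf("  %s / %s: n = %d, best error model %s, best OU model %s\n",
                  v, tn, res$n, res$pgls$error_model, res$best_ou))
    }
  }
  invisible(x)
}

#' Summarize a study manifest as a species funnel
#'
#' @param report A [run_study()] report.
#' @param variant,trait Which manifest to summarize.
#' @return Tibble with counts: loaded, analysed and per-reason drops
#'   (loaded = analysed + dropped).
#' @export
manifest_summary <- function(report, variant = 1L, trait = 1L) {
  man <- report$manifest[[variant]][[trait]]
  drops <- table(man$drop_reason[!man$analysed])
  tibble(stage = c("loaded", "analysed", names(drops)),
         n = c(nrow(man), sum(man$analysed), as.integer(drops)))
}
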