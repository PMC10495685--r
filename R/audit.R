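#' Full consistency audit of a metabolic model
#'
#' Runs the whole quality-control pipeline in order — internal/external
#' split, stoichiometric consistency (sequential minimal relaxation),
#' elemental balance, leak/siphon testing, flux consistency, thermodynamic
#' flux consistency — and summarizes the per-category counts the way model
#' comparison tables report them (reactions and metabolites per consistency
#' class). A model is ready for flux balance analysis when all internal
#' reactions are stoichiometrically and flux consistent and all external
#' reactions are flux consistent.
#'
#' @param model a [metabolic_model()] or a path readable by [read_model()].
#' @param criterion omission criterion for the stoichiometric stage.
#' @param seed seed forwarded to the randomized stages (recorded in the
#'   report).
#' @param prefixes external-id prefixes for [split_internal_external()].
#' @inheritParams solve_cardinality
#' @param ... passed to the stage functions.
#' @return An `audit_report`: a `counts` tibble (`property`, `value`), the
#'   underlying stage results, and `fba_ready` (logical).
#' @export
full_audit <- function(model, criterion = c("elemental", "maxnnz"), seed = 1L,
                       prefixes = c("EX_", "DM_", "sink_", "SK_", "biomass"),
                       backend = lp_backend(), ...) {
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "metabolic_model"))
  criterion <- match.arg(criterion)
  part <- split_internal_external(model, prefixes = prefixes)
  stoich <- find_stoich_consistent_subset(model, criterion = criterion,
                                          partition = part, backend = backend,
                                          ...)
  elem <- if (!is.null(model$met_formula)) {
    elemental_imbalance(model, part)
  } else NULL
  leaks <- find_leaks_siphons(model, closed = TRUE, partition = part,
                              backend = backend)
  flux <- find_flux_consistent_subset(model, backend = backend)
  thermo <- find_thermo_flux_consistent_subset(model, partition = part,
                                               flux = flux, seed = seed,
                                               backend = backend)
  S <- model$S != 0
  n <- ncol(S); m <- nrow(S)
  internal <- part$internal; external <- part$external
  stoich_ok <- stoich$consistent
  flux_ok <- flux$index
  thermo_ok <- thermo$index
  touch <- function(cols) {
    if (length(cols) == 0L) return(rep(FALSE, m))
    Matrix::rowSums(S[, cols, drop = FALSE]) > 0
  }
  leak_idx <- match(leaks$leaks, model$met_ids)
  siphon_idx <- match(leaks$siphons, model$met_ids)
  # reactions carrying the leak (siphon) modes; zero when nothing leaks
  excl_rxns <- function(mode, mets) {
    if (length(mets) == 0L || is.null(mode$x)) return(0L)
    v <- mode$x[seq_len(n)]
    sum(abs(v) > 1e-6)
  }
  met_balanced <- if (is.null(elem)) NA_integer_ else {
    bal_rxn <- match(elem$rxn_id[elem$status == "balanced"], model$rxn_ids)
    sum(touch(bal_rxn) & !touch(setdiff(internal, bal_rxn)))
  }
  counts <- tibble::tribble(
    ~property, ~value,
    "reactions", n,
    "internal_reactions", length(internal),
    "stoich_consistent_rxns", length(stoich_ok),
    "elementally_balanced_rxns",
      if (is.null(elem)) NA_integer_ else sum(elem$status == "balanced"),
    "omitted_rxns", length(stoich$omitted),
    "stoich_and_flux_consistent_rxns", length(intersect(stoich_ok, flux_ok)),
    "stoich_not_flux_consistent_rxns", length(setdiff(stoich_ok, flux_ok)),
    "stoich_and_thermo_consistent_rxns", length(intersect(stoich_ok, thermo_ok)),
    "stoich_not_thermo_consistent_rxns", length(setdiff(stoich_ok, thermo_ok)),
    "reactions_exclusive_to_leaks", excl_rxns(leaks$leak_mode, leaks$leaks),
    "reactions_exclusive_to_siphons",
      excl_rxns(leaks$siphon_mode, leaks$siphons),
    "external_reactions", length(external),
    "external_flux_consistent_rxns", length(intersect(external, flux_ok)),
    "metabolites", m,
    "stoich_consistent_mets",
      sum(stoich$metabolites$label == "stoich_consistent"),
    "elementally_balanced_mets", met_balanced,
    "mets_not_stoich_consistent",
      sum(stoich$metabolites$label == "not_consistent"),
    "omitted_mets", sum(stoich$metabolites$label == "omitted"),
    "stoich_and_flux_consistent_mets",
      sum(touch(intersect(stoich_ok, flux_ok))),
    "stoich_and_thermo_consistent_mets",
      sum(touch(intersect(stoich_ok, thermo_ok))),
    "leak_metabolites", length(leaks$leaks),
    "siphon_metabolites", length(leaks$siphons),
    "external_mets",
      sum(stoich$metabolites$label == "external")
  )
  fba_ready <- setequal(intersect(stoich_ok, flux_ok), internal) &&
    all(external %in% flux_ok)
  structure(list(
    counts = counts, partition = part, stoich = stoich, elemental = elem,
    leaks = leaks, flux = flux, thermo = thermo,
    fba_ready = fba_ready, seed = seed, backend = backend,
    version = as.character(utils::packageVersion("cardopt"))
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  df <- as.data.frame(x$counts)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-36s %s\n", df$property[i], format(df$value[i])))
  }
  cat(sprintf("  FBA-ready: %s\n", x$fba_ready))
  invisible(x)
}

# cross-footing sanity checks on an audit report; returns character(0) when
# every nesting relation holds
audit_crossfoot <- function(report) {
  v <- setNames(report$counts$value, report$counts$property)
  bad <- character(0)
  chk <- function(cond, msg) if (!is.na(cond) && !cond) bad <<- c(bad, msg)
  chk(v["stoich_consistent_rxns"] <= v["internal_reactions"],
      "stoich consistent > internal")
  chk(v["stoich_and_flux_consistent_rxns"] <= v["stoich_consistent_rxns"],
      "stoich+flux > stoich")
  chk(v["stoich_and_thermo_consistent_rxns"] <=
        v["stoich_and_flux_consistent_rxns"],
      "thermo > flux")
  chk(v["external_flux_consistent_rxns"] <= v["external_reactions"],
      "external flux consistent > external")
  chk(v["stoich_and_flux_consistent_rxns"] +
        v["stoich_not_flux_consistent_rxns"] == v["stoich_consistent_rxns"],
      "flux split does not foot")
  bad
}
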