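#' Construct a metabolic model
#'
#' The canonical in-memory representation: a sparse stoichiometric matrix `S`
#' (metabolites in rows, reactions in columns) with flux bounds `lb`, `ub`,
#' steady-state right-hand side `b` (usually zero), a linear objective `obj`,
#' and optional per-metabolite elemental formulae and charges.
#'
#' @param S stoichiometric matrix (anything coercible to a sparse `Matrix`),
#'   `m` metabolites by `n` reactions.
#' @param lb,ub flux bounds, length `n`; missing values default to -1000/1000.
#' @param b steady-state right-hand side, length `m`, default zero.
#' @param obj linear objective coefficients, length `n`, default zero.
#' @param met_ids,rxn_ids unique identifier vectors (defaults taken from
#'   `dimnames(S)` when present).
#' @param met_formula optional character vector of elemental formulae
#'   (`NA` = unknown).
#' @param met_charge optional integer vector of charges (`NA` = unknown).
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(S, lb = NULL, ub = NULL, b = NULL, obj = NULL,
                            met_ids = NULL, rxn_ids = NULL,
                            met_formula = NULL, met_charge = NULL) {
  S <- as_sparse_C(S)
  m <- nrow(S); n <- ncol(S)
  met_ids <- met_ids %||% rownames(S) %||% paste0("m", seq_len(m))
  rxn_ids <- rxn_ids %||% colnames(S) %||% paste0("r", seq_len(n))
  lb <- rep_len(if (is.null(lb)) -1000 else as.numeric(lb), n)
  ub <- rep_len(if (is.null(ub)) 1000 else as.numeric(ub), n)
  lb[is.na(lb)] <- -1000; ub[is.na(ub)] <- 1000
  b <- rep_len(if (is.null(b)) 0 else as.numeric(b), m)
  obj <- rep_len(if (is.null(obj)) 0 else as.numeric(obj), n)
  if (length(met_ids) != m || length(rxn_ids) != n) {
    stop("identifier lengths do not match the matrix dimensions")
  }
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  if (any(lb > ub)) stop("lb > ub for reaction(s): ",
                         paste(rxn_ids[lb > ub], collapse = ", "))
  if (!is.null(met_formula)) met_formula <- rep_len(as.character(met_formula), m)
  if (!is.null(met_charge)) met_charge <- rep_len(as.integer(met_charge), m)
  dimnames(S) <- list(met_ids, rxn_ids)
  structure(
    list(S = S, lb = lb, ub = ub, b = b, obj = obj,
         met_ids = met_ids, rxn_ids = rxn_ids,
         met_formula = met_formula, met_charge = met_charge),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model: %d metabolites x %d reactions, %d nonzeros>\n",
              nrow(x$S), ncol(x$S), Matrix::nnzero(x$S)))
  if (!is.null(x$met_formula)) {
    cat(sprintf("  formulae for %d/%d metabolites\n",
                sum(!is.na(x$met_formula)), nrow(x$S)))
  }
  invisible(x)
}

#' @export
dim.metabolic_model <- function(x) dim(x$S)

#' Split reactions into heuristically internal and external sets
#'
#' A column is labelled external when it has exactly one nonzero
#' stoichiometric coefficient (net mass transfer across the boundary), or
#' when its reaction id matches one of the conventional exchange/demand/sink
#' prefixes. All-zero columns are flagged external with a warning. The split
#' is heuristic: naming conventions tend to underestimate the true external
#' set, and the prefix list is configurable.
#'
#' @param model a [metabolic_model()].
#' @param prefixes id prefixes treated as external (matched
#'   case-insensitively).
#' @return A `stoich_partition` with integer index vectors `internal` and
#'   `external` and a per-reaction `reason` tibble.
#' @export
split_internal_external <- function(model,
                                    prefixes = c("EX_", "DM_", "sink_", "SK_",
                                                 "biomass")) {
  stopifnot(inherits(model, "metabolic_model"))
  nnz <- Matrix::colSums(model$S != 0)
  single <- nnz == 1L
  empty <- nnz == 0L
  if (any(empty)) {
    warning("all-zero reaction column(s) flagged external: ",
            paste(model$rxn_ids[empty], collapse = ", "))
  }
  rx <- paste0("^(", paste(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", prefixes),
                           collapse = "|"), ")")
  by_prefix <- grepl(rx, model$rxn_ids, ignore.case = TRUE)
  ext <- single | empty | by_prefix
  reason <- dplyr::case_when(
    empty ~ "empty column",
    single ~ "single nonzero",
    by_prefix ~ "id prefix",
    .default = "internal"
  )
  structure(
    list(internal = unname(which(!ext)), external = unname(which(ext)),
         reason = tibble::tibble(rxn_id = model$rxn_ids,
                                 external = ext, reason = reason)),
    class = "stoich_partition"
  )
}

#' @export
print.stoich_partition <- function(x, ...) {
  cat(sprintf("<stoich_partition: %d internal, %d external reactions>\n",
              length(x$internal), length(x$external)))
  invisible(x)
}

# internal submatrix N and external submatrix B
model_N <- function(model, partition) model$S[, partition$internal, drop = FALSE]
model_B <- function(model, partition) model$S[, partition$external, drop = FALSE]

# zero out the bounds of the external reactions ("closed" network)
close_externals <- function(model, partition) {
  model$lb[partition$external] <- 0
  model$ub[partition$external] <- 0
  model
}
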