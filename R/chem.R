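# periodic-table symbols accepted as real elements; anything else uppercase
# (R, X, FULLR, ...) is a pseudo-element marking an incomplete formula
ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U"
)

#' Parse an elemental formula
#'
#' Accepts Hill-notation-like strings such as `"C10H12N5O13P3"`. Multi-letter
#' symbols and multi-digit counts are handled. Tokens that are not periodic
#' table symbols (`R` groups, `X`, `*`, `FULLR`, polymer markers like a
#' trailing `n`) are counted under their own name and set the pseudo-element
#' flag: the formula is incompletely specified and must not be treated as
#' balanced evidence.
#'
#' @param formula a single formula string.
#' @return A list with `counts` (named numeric vector of element counts) and
#'   `pseudo` (`TRUE` when any pseudo-element token is present).
#' @examples
#' parse_formula("H2O")
#' parse_formula("C40H66N7O17P3SR")$pseudo
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || formula == "") {
    stop("empty formula")
  }
  s <- formula
  counts <- numeric(0)
  pseudo <- FALSE
  pos <- 1L
  add <- function(sym, k) {
    counts[sym] <<- (if (sym %in% names(counts)) counts[[sym]] else 0) + k
  }
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexec("^([A-Z][a-z]*|\\*)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || m[1] == "") {
      stop("cannot parse formula `", formula, "` at position ", pos,
           " (near `", substr(s, pos, pos + 3L), "`)")
    }
    sym <- m[2]
    k <- if (m[3] == "") 1 else as.numeric(m[3])
    if (!sym %in% ELEMENTS) pseudo <- TRUE
    add(sym, k)
    pos <- pos + nchar(m[1])
  }
  list(counts = counts, pseudo = pseudo)
}

# element-by-metabolite count matrix for a model; metabolites without a
# usable formula get NA columns, pseudo-element formulae are flagged
element_table <- function(model) {
  m <- nrow(model$S)
  form <- model$met_formula %||% rep(NA_character_, m)
  parsed <- lapply(form, function(f) {
    if (is.na(f) || f == "") return(NULL)
    tryCatch(parse_formula(f), error = function(e) NULL)
  })
  pseudo <- vapply(parsed, function(p) !is.null(p) && p$pseudo, logical(1))
  known <- !vapply(parsed, is.null, logical(1))
  elements <- sort(unique(unlist(lapply(parsed[known], function(p) {
    names(p$counts)
  }))))
  E <- matrix(0, length(elements), m, dimnames = list(elements, model$met_ids))
  for (i in which(known)) {
    E[names(parsed[[i]]$counts), i] <- parsed[[i]]$counts
  }
  list(E = E, known = known, pseudo = pseudo, elements = elements)
}

#' Per-reaction elemental balance of the internal reactions
#'
#' For every internal reaction the imbalance of each element `e` is
#' `sum_i S[i, j] * count_e(i)`. A reaction is `balanced` when every element
#' imbalance is zero and no participant carries a pseudo-element or missing
#' formula; it is `undetermined` (never silently "balanced") when any
#' participant's formula is missing or incompletely specified; otherwise it
#' is `imbalanced`. Charge imbalance is computed alongside when charges are
#' present but does not affect the status.
#'
#' @param model a [metabolic_model()].
#' @param partition a [split_internal_external()] partition (computed when
#'   omitted).
#' @param ignore_protons drop hydrogen from the balance check (protons are
#'   frequently misbooked in reconstructions); default `FALSE`.
#' @param tol numeric tolerance for a zero imbalance.
#' @return A tibble with one row per internal reaction: `rxn_id`, `status`,
#'   `imbalance` (list column of named per-element imbalances for imbalanced
#'   reactions) and `charge_imbalance`.
#' @export
elemental_imbalance <- function(model, partition = split_internal_external(model),
                                ignore_protons = FALSE, tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  et <- element_table(model)
  internal <- partition$internal
  N <- model$S[, internal, drop = FALSE]
  elements <- et$elements
  if (ignore_protons) elements <- setdiff(elements, "H")
  imb <- if (length(elements)) {
    as.matrix(et$E[elements, , drop = FALSE] %*% N)
  } else {
    matrix(0, 0, length(internal))
  }
  participants <- lapply(seq_along(internal), function(k) which(N[, k] != 0))
  bad_part <- vapply(participants, function(ii) {
    any(!et$known[ii]) || any(et$pseudo[ii])
  }, logical(1))
  status <- vapply(seq_along(internal), function(k) {
    if (bad_part[k]) return("undetermined")
    if (length(elements) && any(abs(imb[, k]) > tol)) return("imbalanced")
    "balanced"
  }, character(1))
  charge <- rep(NA_real_, length(internal))
  if (!is.null(model$met_charge)) {
    ch <- model$met_charge
    has_ch <- !is.na(ch)
    ch0 <- ifelse(has_ch, ch, 0)
    charge <- as.numeric(ch0 %*% N)
    all_known <- vapply(participants, function(ii) all(has_ch[ii]), logical(1))
    charge[!all_known] <- NA_real_
  }
  tibble::tibble(
    rxn_id = model$rxn_ids[internal],
    status = status,
    imbalance = lapply(seq_along(internal), function(k) {
      if (status[k] != "imbalanced") return(numeric(0))
      v <- imb[, k]
      v[abs(v) > tol]
    }),
    charge_imbalance = charge
  )
}
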