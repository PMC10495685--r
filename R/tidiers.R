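#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a consistency partition
#'
#' @param x a `consistency_partition` from [find_stoich_consistent_subset()].
#' @param which `"reactions"` (default) or `"metabolites"`.
#' @param ... unused.
#' @return A tibble of identifiers and labels.
#' @method tidy consistency_partition
#' @export
tidy.consistency_partition <- function(x, which = c("reactions", "metabolites"),
                                       ...) {
  switch(match.arg(which), reactions = x$reactions,
         metabolites = x$metabolites)
}

#' @method glance consistency_partition
#' @export
glance.consistency_partition <- function(x, ...) {
  tibble::tibble(
    n_consistent = length(x$consistent),
    n_inconsistent = length(x$inconsistent),
    n_omitted = length(x$omitted),
    n_external = length(x$external),
    rounds = nrow(x$log)
  )
}

#' Tidy a cardinality solution
#'
#' @param x a `cardinality_solution` from [solve_cardinality()].
#' @param ... unused.
#' @return A tibble with one row per variable in a cardinality block:
#'   `name`, `block`, `value`, `in_support`.
#' @method tidy cardinality_solution
#' @export
tidy.cardinality_solution <- function(x, ...) {
  prob <- x$problem
  idx <- c(prob$minimize, prob$maximize)
  block <- c(rep("minimize", length(prob$minimize)),
             rep("maximize", length(prob$maximize)))
  tibble::tibble(
    name = prob$names[idx], block = block,
    value = if (is.null(x$x)) NA_real_ else x$x[idx],
    in_support = idx %in% c(x$support_min, x$support_max)
  )
}

#' @method glance cardinality_solution
#' @export
glance.cardinality_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    card_min = length(x$support_min),
    card_max = length(x$support_max),
    iterations = x$iterations,
    lp_count = x$lp_count,
    feas_violation = x$feas_violation,
    max_descent_violation = if (length(x$descent)) max(x$descent) else NA_real_
  )
}

#' @method tidy relaxation_solution
#' @export
tidy.relaxation_solution <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$relaxed_bounds, id = .data$rxn_id,
                     constraint = ifelse(.data$lower_relax > 0,
                                         "lower_bound", "upper_bound"),
                     relaxation = pmax(.data$lower_relax, .data$upper_relax)),
    dplyr::transmute(x$relaxed_steady_state, id = .data$met_id,
                     constraint = "steady_state", relaxation = .data$relax)
  )
}

#' @method glance relaxation_solution
#' @export
glance.relaxation_solution <- function(x, ...) {
  tibble::tibble(
    n_lower = sum(x$p > 0), n_upper = sum(x$q > 0),
    n_steady_state = sum(x$r != 0), total_card = x$total_card,
    relaxed_feasible = x$relaxed_feasible
  )
}

#' @method tidy sparse_fba
#' @export
tidy.sparse_fba <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(rxn_id = x$support,
                   flux = x$v[x$support_index]),
    dplyr::select(x$removability, rxn_id = "name", "removable"),
    by = "rxn_id"
  )
}

#' @method glance sparse_fba
#' @export
glance.sparse_fba <- function(x, ...) {
  tibble::tibble(
    rho_star = x$rho_star, support_size = length(x$support),
    n_removable = sum(x$removability$removable), lp_count = x$lp_count
  )
}

#' @method tidy audit_report
#' @export
tidy.audit_report <- function(x, ...) x$counts

#' @method glance audit_report
#' @export
glance.audit_report <- function(x, ...) {
  tibble::tibble(fba_ready = x$fba_ready, seed = x$seed,
                 backend = x$backend, version = x$version)
}

#' @method tidy thermo_subset
#' @export
tidy.thermo_subset <- function(x, ...) x$directions

#' @method tidy stoich_partition
#' @export
tidy.stoich_partition <- function(x, ...) x$reason

#' Bar chart of audit-report category counts
#'
#' @param object an `audit_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot audit_report
#' @export
autoplot.audit_report <- function(object, ...) {
  df <- dplyr::filter(object$counts, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value,
    y = stats::reorder(.data$property, .data$value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "count", y = NULL,
                  title = "Model consistency audit") +
    ggplot2::theme_minimal()
}

#' Objective trace of a DCA solve
#'
#' Plots the approximate cardinality objective per outer iteration; within
#' each iteration the DCA step is guaranteed non-ascending at that
#' iteration's sharpness.
#'
#' @param object a `cardinality_solution`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cardinality_solution
#' @export
autoplot.cardinality_solution <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace),
                       objective = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "outer iteration", y = "approximate objective",
                  title = "DCA objective trace") +
    ggplot2::theme_minimal()
}
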