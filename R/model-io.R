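#' Read a metabolic model
#'
#' Supported formats: SBML Level 3 with the FBC version 2 extension
#' (`"sbml"`), the cobrapy-style JSON dialect (`"json"`), and a plain-text
#' TSV triplet of `(met_id, rxn_id, coefficient)` with companion bounds and
#' metabolite tables (`"tsv"`). Missing bounds default to -1000/1000 and the
#' steady-state right-hand side defaults to zero.
#'
#' @param path model file. For `"tsv"`, the stoichiometry triplet file; the
#'   bounds table defaults to `<stem>_bounds.tsv` and the optional metabolite
#'   table (`met_id`, `formula`, `charge`) to `<stem>_mets.tsv`.
#' @param format one of `"auto"`, `"sbml"`, `"json"`, `"tsv"`; `"auto"` picks
#'   by file extension (`.xml`/`.sbml`, `.json`, `.tsv`).
#' @param bounds,mets override the companion TSV paths.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "json", "tsv"),
                       bounds = NULL, mets = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml", json = "json", tsv = "tsv",
                     stop("cannot guess the model format of ", path))
  }
  switch(format,
    sbml = read_model_sbml(path),
    json = read_model_json(path),
    tsv = read_model_tsv(path, bounds = bounds, mets = mets)
  )
}

#' Write a metabolic model
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @param format `"sbml"`, `"json"` or `"tsv"` (for `"tsv"` the companion
#'   `<stem>_bounds.tsv` and `<stem>_mets.tsv` files are written alongside).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml", "tsv")) {
  stopifnot(inherits(model, "metabolic_model"))
  switch(match.arg(format),
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path),
    tsv = write_model_tsv(model, path)
  )
  invisible(path)
}

## ---- JSON (cobrapy dialect) ------------------------------------------------

read_model_json <- function(path) {
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE),
                error = function(e) stop("malformed JSON model ", path, ": ",
                                         conditionMessage(e)))
  if (is.null(j$metabolites) || is.null(j$reactions)) {
    stop("malformed JSON model ", path,
         ": missing `metabolites` or `reactions`")
  }
  met_ids <- vapply(j$metabolites, function(m) as.character(m$id), character(1))
  form <- vapply(j$metabolites, function(m) {
    f <- m$formula
    if (is.null(f) || length(f) == 0L || identical(f, "")) NA_character_
    else as.character(f)
  }, character(1))
  chg <- vapply(j$metabolites, function(m) {
    if (is.null(m$charge)) NA_integer_ else as.integer(m$charge)
  }, integer(1))
  rxn_ids <- vapply(j$reactions, function(r) as.character(r$id), character(1))
  met_index <- setNames(seq_along(met_ids), met_ids)
  ti <- list(); tj <- list(); tx <- list()
  for (k in seq_along(j$reactions)) {
    mm <- j$reactions[[k]]$metabolites
    if (length(mm) == 0L) next
    ids <- names(mm)
    if (any(!ids %in% met_ids)) {
      stop("malformed JSON model ", path, ": reaction ", rxn_ids[k],
           " references unknown metabolite ",
           ids[!ids %in% met_ids][1])
    }
    ti[[k]] <- unname(met_index[ids])
    tj[[k]] <- rep(k, length(ids))
    tx[[k]] <- as.numeric(unlist(mm))
  }
  num_or <- function(field, default) {
    vapply(j$reactions, function(r) {
      v <- r[[field]]
      if (is.null(v) || length(v) == 0L || is.na(v)) default else as.numeric(v)
    }, numeric(1))
  }
  S <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(length(met_ids), length(rxn_ids)))
  metabolic_model(
    S, lb = num_or("lower_bound", -1000), ub = num_or("upper_bound", 1000),
    obj = num_or("objective_coefficient", 0),
    met_ids = met_ids, rxn_ids = rxn_ids,
    met_formula = if (all(is.na(form))) NULL else form,
    met_charge = if (all(is.na(chg))) NULL else chg
  )
}

write_model_json <- function(model, path) {
  S <- as(model$S, "TsparseMatrix")
  mets <- purrr::map(seq_len(nrow(S)), function(i) {
    m <- list(id = model$met_ids[i])
    if (!is.null(model$met_formula) && !is.na(model$met_formula[i])) {
      m$formula <- model$met_formula[i]
    }
    if (!is.null(model$met_charge) && !is.na(model$met_charge[i])) {
      m$charge <- model$met_charge[i]
    }
    m
  })
  by_col <- split(data.frame(i = S@i + 1L, x = S@x), S@j + 1L)
  rxns <- purrr::map(seq_len(ncol(S)), function(k) {
    entries <- by_col[[as.character(k)]]
    stoich <- if (is.null(entries)) setNames(list(), character(0)) else {
      setNames(as.list(entries$x), model$met_ids[entries$i])
    }
    list(id = model$rxn_ids[k], metabolites = stoich,
         lower_bound = model$lb[k], upper_bound = model$ub[k],
         objective_coefficient = model$obj[k])
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns, version = "1"),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- TSV triplet -----------------------------------------------------------

companion <- function(path, suffix) {
  file.path(dirname(path),
            paste0(sub("\\.[^.]*$", "", basename(path)), suffix))
}

read_model_tsv <- function(path, bounds = NULL, mets = NULL) {
  tri <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("met_id", "rxn_id", "coefficient")
  if (!all(need %in% names(tri))) {
    stop("malformed TSV model ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  met_ids <- unique(tri$met_id)
  rxn_ids <- unique(tri$rxn_id)
  S <- Matrix::sparseMatrix(i = match(tri$met_id, met_ids),
                            j = match(tri$rxn_id, rxn_ids),
                            x = as.numeric(tri$coefficient),
                            dims = c(length(met_ids), length(rxn_ids)))
  lb <- NULL; ub <- NULL
  bounds <- bounds %||% companion(path, "_bounds.tsv")
  if (file.exists(bounds)) {
    bt <- utils::read.delim(bounds, stringsAsFactors = FALSE)
    if (!all(c("rxn_id", "lb", "ub") %in% names(bt))) {
      stop("malformed bounds TSV ", bounds, ": need rxn_id, lb, ub")
    }
    idx <- match(rxn_ids, bt$rxn_id)
    lb <- bt$lb[idx]; ub <- bt$ub[idx]
  }
  form <- chg <- NULL
  mets <- mets %||% companion(path, "_mets.tsv")
  if (file.exists(mets)) {
    mt <- utils::read.delim(mets, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    idx <- match(met_ids, mt$met_id)
    if ("formula" %in% names(mt)) form <- as.character(mt$formula[idx])
    if ("charge" %in% names(mt)) chg <- as.integer(mt$charge[idx])
  }
  metabolic_model(S, lb = lb, ub = ub, met_ids = met_ids, rxn_ids = rxn_ids,
                  met_formula = form, met_charge = chg)
}

write_model_tsv <- function(model, path) {
  S <- as(model$S, "TsparseMatrix")
  ord <- order(S@j, S@i)
  utils::write.table(
    data.frame(met_id = model$met_ids[S@i[ord] + 1L],
               rxn_id = model$rxn_ids[S@j[ord] + 1L],
               coefficient = S@x[ord]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(rxn_id = model$rxn_ids, lb = model$lb, ub = model$ub),
    companion(path, "_bounds.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  if (!is.null(model$met_formula) || !is.null(model$met_charge)) {
    utils::write.table(
      data.frame(met_id = model$met_ids,
                 formula = model$met_formula %||% NA,
                 charge = model$met_charge %||% NA),
      companion(path, "_mets.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
}

## ---- SBML Level 3 + FBC v2 -------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(class(mdl)[1]) || inherits(mdl, "xml_missing")) {
    stop("malformed SBML ", path, ": no <model> element")
  }
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  sp_formula <- xml2::xml_attr(species, "fbc:chemicalFormula", ns = ns)
  sp_charge <- suppressWarnings(as.integer(
    xml2::xml_attr(species, "fbc:charge", ns = ns)))
  keep <- !sp_boundary
  met_ids <- sp_id[keep]
  met_index <- setNames(seq_along(met_ids), met_ids)
  rxns <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  n <- length(rxns)
  lb <- numeric(n); ub <- numeric(n)
  ti <- list(); tj <- list(); tx <- list()
  for (k in seq_len(n)) {
    r <- rxns[[k]]
    refs <- function(tag, sgn) {
      nodes <- xml2::xml_find_all(r, paste0("./s:", tag, "/s:speciesReference"),
                                  ns)
      if (length(nodes) == 0L) return(NULL)
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      data.frame(id = xml2::xml_attr(nodes, "species"), coef = sgn * st)
    }
    df <- rbind(refs("listOfReactants", -1), refs("listOfProducts", 1))
    if (!is.null(df)) {
      df <- df[df$id %in% met_ids, , drop = FALSE]
      if (nrow(df)) {
        agg <- tapply(df$coef, df$id, sum)
        ti[[k]] <- unname(met_index[names(agg)])
        tj[[k]] <- rep(k, length(agg))
        tx[[k]] <- as.numeric(agg)
      }
    }
    lbref <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns = ns)
    ubref <- xml2::xml_attr(r, "fbc:upperFluxBound", ns = ns)
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb[k] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else {
      if (rev) -1000 else 0
    }
    ub[k] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
  }
  obj <- rep(0, n)
  fobj <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (length(fobj)) {
    orx <- xml2::xml_attr(fobj, "fbc:reaction", ns = ns)
    oco <- as.numeric(xml2::xml_attr(fobj, "fbc:coefficient", ns = ns))
    obj[match(orx, rxn_ids)] <- oco
  }
  S <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(length(met_ids), n))
  form <- sp_formula[keep]
  metabolic_model(S, lb = lb, ub = ub, obj = obj, met_ids = met_ids,
                  rxn_ids = rxn_ids,
                  met_formula = if (all(is.na(form))) NULL else form,
                  met_charge = {
                    ch <- sp_charge[keep]
                    if (all(is.na(ch))) NULL else ch
                  })
}

write_model_sbml <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  bounds <- sort(unique(c(model$lb, model$ub)))
  pid <- setNames(sprintf("par_b%d", seq_along(bounds)), num(bounds))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  S <- model$S
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
    SBML_NS, FBC_NS)
  w('  <model id="model" fbc:strict="true">')
  w('    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(S))) {
    extra <- ""
    if (!is.null(model$met_formula) && !is.na(model$met_formula[i])) {
      extra <- sprintf(' fbc:chemicalFormula="%s"', esc(model$met_formula[i]))
    }
    if (!is.null(model$met_charge) && !is.na(model$met_charge[i])) {
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', model$met_charge[i]))
    }
    w('      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      esc(model$met_ids[i]), extra)
  }
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (k in seq_along(bounds)) {
    w('      <parameter id="%s" value="%s" constant="true"/>',
      unname(pid[k]), num(bounds[k]))
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  St <- as(S, "TsparseMatrix")
  for (k in seq_len(ncol(S))) {
    sel <- which(St@j + 1L == k)
    coefs <- St@x[sel]; rows <- St@i[sel] + 1L
    w('      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(model$rxn_ids[k]), if (model$lb[k] < 0) "true" else "false",
      unname(pid[num(model$lb[k])]), unname(pid[num(model$ub[k])]))
    rect <- rows[coefs < 0]; prod <- rows[coefs > 0]
    if (length(rect)) {
      w('        <listOfReactants>')
      for (ii in seq_along(rect)) {
        w('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(model$met_ids[rect[ii]]), num(-coefs[coefs < 0][ii]))
      }
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (ii in seq_along(prod)) {
        w('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(model$met_ids[prod[ii]]), num(coefs[coefs > 0][ii]))
      }
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  if (any(model$obj != 0)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    for (k in which(model$obj != 0)) {
      w('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
        esc(model$rxn_ids[k]), num(model$obj[k]))
    }
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
}

#' Write a machine-readable report
#'
#' Serializes any result object with a [generics::tidy()] method (consistency
#' partitions, audit reports, relaxation solutions, ...) to JSON or TSV.
#' Reports list identifiers, never internal indices.
#'
#' @param x a result object with a `tidy()` method (or a data frame).
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  tb <- if (is.data.frame(x)) x else generics::tidy(x)
  if (format == "json") {
    payload <- list(rows = tb)
    if (!is.null(attr(x, "meta"))) payload$meta <- attr(x, "meta")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", na = "null")
  } else {
    utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
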