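#' Stoichiometric network models
#'
#' A `network_model` bundles an ordered metabolite table, an ordered
#' reaction table (with stoichiometries, reversibilities, flux bounds and
#' optional standard transformed Gibbs energies), a regulation table of
#' allosteric effector edges, and the assembled stoichiometric matrix `S`.
#' Rows of `S` are the *balanced* metabolites (extracellular and currency
#' species are excluded from steady-state balances); columns follow the
#' reaction order.
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`
#'   (`"cytosol"` or `"extracellular"`), `conc_lb`, `conc_ub` (molar),
#'   `is_balanced` (logical), `measured` (logical).
#' @param reactions tibble with columns `id`, `enzyme_label`, `stoich`
#'   (list-column of named numeric vectors, metabolite id -> signed
#'   coefficient), `reversible`, `lb`, `ub` (mmol/gCDW/h), `dg0_prime`
#'   (kJ/mol, `NA` if unknown), `is_exchange`.
#' @param regulation optional tibble with `reaction_id`, `metabolite_id`,
#'   `sign` (+1 activator, -1 inhibitor).
#' @param objective_id id of the growth/biomass reaction.
#' @return an object of class `network_model`.
#' @export
network_model <- function(metabolites, reactions, regulation = NULL,
                          objective_id = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (nrow(reactions) == 0L) stop("model has zero reactions")
  if (any(metabolites$conc_lb <= 0 | metabolites$conc_ub <= 0))
    stop("concentration bounds must be strictly positive")
  if (any(metabolites$conc_lb >= metabolites$conc_ub))
    stop("concentration bounds must satisfy lower < upper")

  # every referenced metabolite must resolve
  refs <- unique(unlist(lapply(reactions$stoich, names)))
  dangling <- setdiff(refs, metabolites$id)
  if (length(dangling) > 0L)
    stop("reactions reference unknown metabolites: ",
         paste(dangling, collapse = ", "))
  if (any(lengths(reactions$stoich) == 0L))
    stop("empty stoichiometry in reaction(s): ",
         paste(reactions$id[lengths(reactions$stoich) == 0L], collapse = ", "))

  if (is.null(regulation))
    regulation <- tibble::tibble(reaction_id = character(),
                                 metabolite_id = character(), sign = numeric())

  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          regulation = tibble::as_tibble(regulation),
                          objective_id = objective_id),
                     class = "network_model")
  model$S <- build_stoich_matrix(model)

  # non-exchange reactions must engage the balanced network
  bal <- metabolites$id[metabolites$is_balanced]
  n_bal <- vapply(reactions$stoich, function(s) sum(names(s) %in% bal), 0L)
  offenders <- reactions$id[!reactions$is_exchange & n_bal < 2L]
  if (length(offenders) > 0L)
    stop("non-exchange reactions must involve >= 2 balanced metabolites: ",
         paste(offenders, collapse = ", "))
  model
}

# S over balanced metabolites only (rows) x reactions (cols), model order
build_stoich_matrix <- function(model) {
  bal <- model$metabolites$id[model$metabolites$is_balanced]
  S <- matrix(0, length(bal), nrow(model$reactions),
              dimnames = list(bal, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    keep <- names(s) %in% bal
    if (any(keep)) S[names(s)[keep], j] <- s[keep]
  }
  S
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (", nrow(x$S), " balanced)\n", sep = "")
  cat("  objective: ", x$objective_id %||% "<none>", "\n", sep = "")
  invisible(x)
}

## ---- reaction-equation strings --------------------------------------------

#' Parse a reaction equation string
#'
#' Understands the dialect `"2 A + B -> C"`; `"<->"` (or `"<=>"`) marks a
#' reversible reaction.  Either side may be empty (exchange with the
#' environment).
#'
#' @param eq equation string.
#' @return list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  rev_arrow <- grepl("<->|<=>", eq)
  parts <- strsplit(eq, "<->|<=>|-->|->", perl = TRUE)[[1]]
  if (length(parts) > 2L) stop("cannot parse equation: ", eq)
  side <- function(txt, sgn) {
    txt <- trimws(txt)
    if (is.na(txt) || txt == "") return(numeric())
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(length(terms)); nm <- character(length(terms))
    for (k in seq_along(terms)) {
      tk <- strsplit(terms[k], "\\s+")[[1]]
      if (length(tk) == 1L) { out[k] <- sgn; nm[k] <- tk }
      else if (length(tk) == 2L) {
        coef <- suppressWarnings(as.numeric(tk[1]))
        if (is.na(coef)) stop("bad coefficient in term '", terms[k], "' of: ", eq)
        out[k] <- sgn * coef; nm[k] <- tk[2]
      } else stop("bad term '", terms[k], "' in: ", eq)
    }
    stats::setNames(out, nm)
  }
  lhs <- side(parts[1], -1)
  rhs <- side(if (length(parts) == 2L) parts[2] else NA_character_, +1)
  st <- c(lhs, rhs)
  # merge duplicated species across sides
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  list(stoich = stats::setNames(as.numeric(st), names(st)), reversible = rev_arrow)
}

format_equation <- function(stoich, reversible) {
  fmt <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, scientific = FALSE), names(v))),
          collapse = " + ")
  }
  lhs <- fmt(stoich[stoich < 0]); rhs <- fmt(stoich[stoich > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

## ---- input / output -------------------------------------------------------

#' Load a network model from disk
#'
#' Two formats are supported.  `"tabular"` expects a directory with
#' `metabolites.csv` and `reactions.csv` (optional `regulation.csv`), the
#' dialect written by [write_model_tabular()].  `"sbml"` reads an SBML
#' Level 3 file (ids, names, compartments, stoichiometries, reversibility
#' and flux bounds), which serves as an import hook for genome-scale
#' models.
#'
#' @param path directory (tabular) or file (sbml).
#' @param format `"tabular"` or `"sbml"`.
#' @return a validated [network_model()].
#' @export
load_model <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "tabular") load_model_tabular(path) else load_model_sbml(path)
}

load_model_tabular <- function(dir) {
  metf <- file.path(dir, "metabolites.csv")
  rxnf <- file.path(dir, "reactions.csv")
  for (f in c(metf, rxnf))
    if (!file.exists(f)) stop("missing model file: ", f)
  mets <- readr::read_csv(metf, show_col_types = FALSE)
  rxns <- readr::read_csv(rxnf, show_col_types = FALSE)
  need_m <- c("id", "name", "compartment", "conc_lb", "conc_ub", "is_balanced", "measured")
  need_r <- c("id", "enzyme_label", "equation", "lb", "ub", "dg0_prime", "is_exchange")
  if (!all(need_m %in% names(mets)))
    stop("metabolites.csv lacks columns: ", paste(setdiff(need_m, names(mets)), collapse = ", "))
  if (!all(need_r %in% names(rxns)))
    stop("reactions.csv lacks columns: ", paste(setdiff(need_r, names(rxns)), collapse = ", "))
  parsed <- lapply(rxns$equation, parse_equation)
  rxns$stoich <- lapply(parsed, `[[`, "stoich")
  rxns$reversible <- vapply(parsed, `[[`, TRUE, "reversible")
  regf <- file.path(dir, "regulation.csv")
  reg <- if (file.exists(regf)) readr::read_csv(regf, show_col_types = FALSE) else NULL
  obj <- if ("is_objective" %in% names(rxns)) rxns$id[which(rxns$is_objective)][1] else NULL
  if (is.null(obj) || length(obj) == 0L || is.na(obj)) obj <- NULL
  network_model(mets, rxns[setdiff(names(rxns), c("equation", "is_objective"))],
                regulation = reg, objective_id = obj)
}

load_model_sbml <- function(file) {
  if (!file.exists(file)) stop("missing SBML file: ", file)
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) stop("SBML parse failure in '", file, "': ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("SBML file declares no species")
  attr_or <- function(nodes, a, default) {
    v <- xml2::xml_attr(nodes, a); v[is.na(v)] <- default; v
  }
  comp <- xml2::xml_attr(sp, "compartment")
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = attr_or(sp, "name", ""),
    compartment = ifelse(grepl("^e", comp), "extracellular", "cytosol"),
    conc_lb = 1e-7, conc_ub = 1e-1,
    is_balanced = !(xml2::xml_attr(sp, "boundaryCondition") %in% "true") &
      !grepl("^e", comp),
    measured = FALSE)
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("SBML file declares no reactions")
  stoich <- lapply(rx, function(r) {
    rr <- xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)
    pp <- xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)
    co <- c(-as.numeric(attr_or(rr, "stoichiometry", "1")),
            as.numeric(attr_or(pp, "stoichiometry", "1")))
    stats::setNames(co, c(xml2::xml_attr(rr, "species"), xml2::xml_attr(pp, "species")))
  })
  reversible <- xml2::xml_attr(rx, "reversible") %in% "true"
  rxns <- tibble::tibble(
    id = xml2::xml_attr(rx, "id"),
    enzyme_label = attr_or(rx, "name", ""),
    stoich = stoich, reversible = reversible,
    lb = ifelse(reversible, -1000, 0), ub = 1000,
    dg0_prime = NA_real_,
    is_exchange = vapply(stoich, function(s) length(s) == 1L, TRUE) |
      grepl("^(EX_|R_EX_)", xml2::xml_attr(rx, "id")))
  network_model(mets, rxns)
}

#' Write a model in the tabular CSV dialect
#'
#' @param model a [network_model()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_tabular <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(model$metabolites, file.path(dir, "metabolites.csv"))
  rx <- model$reactions
  out <- tibble::tibble(
    id = rx$id, enzyme_label = rx$enzyme_label,
    equation = mapply(format_equation, rx$stoich, rx$reversible),
    lb = rx$lb, ub = rx$ub, dg0_prime = rx$dg0_prime,
    is_exchange = rx$is_exchange,
    is_objective = rx$id %in% (model$objective_id %||% ""))
  readr::write_csv(out, file.path(dir, "reactions.csv"))
  if (nrow(model$regulation) > 0L)
    readr::write_csv(model$regulation, file.path(dir, "regulation.csv"))
  invisible(dir)
}

#' The packaged reduced E. coli L-tryptophan production model
#'
#' A 53-reaction, 59-metabolite reduction of Escherichia coli metabolism
#' covering glycolysis, glycerol metabolism, the methylglyoxal pathway, the
#' TCA cycle, the pentose phosphate pathway, L-serine biosynthesis and
#' aromatic amino acid / L-tryptophan biosynthesis, with exchange reactions
#' for the four perturbation substrates (glycerol, glucose, pyruvate,
#' succinate), product and by-product secretion and gas exchange.  Several
#' linear enzyme segments are lumped; Gibbs energies are curated effective
#' standard transformed values (pH 7.0, ionic strength 0.15 M, typical
#' cofactor poise folded in).  The 45-metabolite measured panel is flagged
#' in the `measured` column.
#'
#' @return a [network_model()].
#' @export
ecoli_trp_model <- function() {
  dir <- system.file("extdata", "ecoli_trp_reduced", package = "fluxcontrol")
  if (dir == "") dir <- file.path("inst", "extdata", "ecoli_trp_reduced")
  load_model(dir, "tabular")
}

## ---- validation ------------------------------------------------------------

#' Validate a network model
#'
#' Report-only check for blocked (all-zero row) metabolites, orphan
#' metabolites referenced by no reaction, inverted flux or concentration
#' bounds and duplicate ids.  An empty tibble means no issues.
#'
#' @param model a [network_model()].
#' @return tibble with columns `type`, `id`, `message`.
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(type, id, msg)
    issues[[length(issues) + 1L]] <<- tibble::tibble(type = type, id = id, message = msg)

  refs <- unique(unlist(lapply(model$reactions$stoich, names)))
  for (m in setdiff(model$metabolites$id, refs))
    add("orphan_metabolite", m, "metabolite referenced by no reaction")
  blocked <- rownames(model$S)[rowSums(abs(model$S)) == 0]
  for (m in blocked) add("blocked_metabolite", m, "balanced metabolite with all-zero row")
  bad <- model$reactions$id[model$reactions$lb > model$reactions$ub]
  for (r in bad) add("inverted_bounds", r, "flux lower bound exceeds upper bound")
  badc <- model$metabolites$id[model$metabolites$conc_lb > model$metabolites$conc_ub]
  for (m in badc) add("inverted_conc_bounds", m, "concentration lower bound exceeds upper")
  if (length(issues) == 0L)
    return(tibble::tibble(type = character(), id = character(), message = character()))
  dplyr::bind_rows(issues)
}

## ---- stoichiometric reduction ---------------------------------------------

#' Reduce the stoichiometric matrix to independent metabolite balances
#'
#' Finds, deterministically in model (row) order, a maximal set of linearly
#' independent balanced-metabolite rows `S_R` and the link matrix `L` with
#' `S = L %*% S_R`.  Dependent rows correspond to conserved moieties (or
#' duplicated balances); they must be eliminated before the lin-log control
#' analysis because the Jacobian of the independent system has to be
#' invertible.
#'
#' @param model a [network_model()], or a plain numeric matrix.
#' @param tol rank tolerance on singular values.
#' @return list of class `reduced_stoichiometry` with `S_R`, `L`,
#'   `independent_ids`, `dependent_ids`.
#' @export
reduce_stoichiometry <- function(model, tol = 1e-9) {
  S <- if (inherits(model, "network_model")) model$S else as.matrix(model)
  if (is.null(rownames(S))) rownames(S) <- paste0("m", seq_len(nrow(S)))
  keep <- logical(nrow(S))
  rk <- 0L
  basis <- matrix(0, 0, ncol(S))
  for (i in seq_len(nrow(S))) {
    cand <- rbind(basis, S[i, ])
    r <- qr(t(cand), tol = tol)$rank
    if (r > rk) { keep[i] <- TRUE; rk <- r; basis <- cand }
  }
  S_R <- S[keep, , drop = FALSE]
  # rows of S lie in the row space of S_R; solve L by least squares
  # (L = S S_R' (S_R S_R')^{-1}, well-posed because S_R has full row rank)
  L <- t(qr.solve(S_R %*% t(S_R), S_R %*% t(S), tol = 1e-12))
  dimnames(L) <- list(rownames(S), rownames(S_R))
  structure(list(S_R = S_R, L = L,
                 independent_ids = rownames(S)[keep],
                 dependent_ids = rownames(S)[!keep]),
            class = "reduced_stoichiometry")
}

#' @export
print.reduced_stoichiometry <- function(x, ...) {
  cat("<reduced_stoichiometry> ", length(x$independent_ids), " independent / ",
      length(x$dependent_ids), " dependent metabolite balances\n", sep = "")
  invisible(x)
}
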