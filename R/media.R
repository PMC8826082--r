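# Medium composition: compounds, ionic constituents, and the gradient design.

#' Constituent and compound vocabularies
#'
#' The minimal medium is mixed from seven pure chemical compounds; in
#' solution these dissociate into eight ionic-form constituents (chemical
#' niches): glucose, K+, PO4(3-), Mg2+, SO4(2-), NH4+, Fe2+ and thiamine.
#' Names are returned in canonical order.
#'
#' @return Character vector of names.
#' @export
constituent_names <- function() {
  c("glucose", "K", "PO4", "Mg", "SO4", "NH4", "Fe", "thiamine")
}

#' @rdname constituent_names
#' @export
compound_names <- function() {
  c("glucose", "K2HPO4", "KH2PO4", "MgSO4", "thiamine_HCl", "FeSO4",
    "(NH4)2SO4")
}

# Stoichiometry of dissociation: rows = constituents, cols = compounds.
# K2HPO4 -> 2 K+ + PO4; KH2PO4 -> K+ + PO4; MgSO4 -> Mg2+ + SO4;
# FeSO4 -> Fe2+ + SO4; (NH4)2SO4 -> 2 NH4+ + SO4; glucose and thiamine
# pass through unchanged.
stoichiometry_matrix <- function() {
  ions <- constituent_names()
  cmp <- compound_names()
  m <- matrix(0, nrow = length(ions), ncol = length(cmp),
              dimnames = list(ions, cmp))
  m["glucose", "glucose"] <- 1
  m["K", "K2HPO4"] <- 2
  m["K", "KH2PO4"] <- 1
  m["PO4", "K2HPO4"] <- 1
  m["PO4", "KH2PO4"] <- 1
  m["Mg", "MgSO4"] <- 1
  m["SO4", "MgSO4"] <- 1
  m["SO4", "FeSO4"] <- 1
  m["SO4", "(NH4)2SO4"] <- 1
  m["NH4", "(NH4)2SO4"] <- 2
  m["Fe", "FeSO4"] <- 1
  m["thiamine", "thiamine_HCl"] <- 1
  m
}

#' Convert a compound mix to ionic-form constituent concentrations
#'
#' Applies the dissociation stoichiometry to a named vector of compound
#' molarities, giving the concentration of each of the eight constituents.
#' The map is linear: `compound_to_ions(a*m1 + b*m2)` equals
#' `a*compound_to_ions(m1) + b*compound_to_ions(m2)` for non-negative
#' weights.
#'
#' @param mix Named numeric vector of compound concentrations (mol/L) over
#'   the seven compounds of [compound_names()]. Missing compounds default
#'   to zero.
#' @return Named numeric vector of length 8 (mol/L), in the order of
#'   [constituent_names()].
#' @examples
#' compound_to_ions(c(K2HPO4 = 0.615))  # K = 1.23, PO4 = 0.615
#' @export
compound_to_ions <- function(mix) {
  mix <- as_compound_mix(mix)
  drop(stoichiometry_matrix() %*% mix)
}

# Validate/normalise a compound mix to the full named vector of 7.
as_compound_mix <- function(mix) {
  if (is.null(names(mix)) && length(mix) == length(compound_names())) {
    names(mix) <- compound_names()
  }
  unknown <- setdiff(names(mix), compound_names())
  if (length(unknown) > 0) {
    stop("unknown compound(s): ", paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(compound_names())), compound_names())
  full[names(mix)] <- as.numeric(mix)
  if (any(!is.finite(full))) stop("compound concentrations must be finite")
  if (any(full < 0)) stop("compound concentrations must be non-negative")
  full
}

#' Working concentrations of the reference minimal medium
#'
#' Compound molarities of the modified M63 minimal medium used as the
#' reference environment (C0): 22.2 mM glucose, 61.5 mM K2HPO4, 38.2 mM
#' KH2PO4, 0.203 mM MgSO4, 15.2 uM thiamine/HCl, 1.8 uM FeSO4 and 15.32 mM
#' (NH4)2SO4.
#'
#' @return Named numeric vector (mol/L) over [compound_names()].
#' @export
m63_mix <- function() {
  c(glucose = 22.2e-3,
    K2HPO4 = 61.5e-3,
    KH2PO4 = 38.2e-3,
    MgSO4 = 0.203e-3,
    thiamine_HCl = 15.2e-6,
    FeSO4 = 1.8e-6,
    `(NH4)2SO4` = 15.32e-3)
}

#' Build the medium-combination design matrix
#'
#' Starting from a reference compound mix (C0), varies the concentration of
#' one compound at a time on a logarithmic scale, producing 28 alternative
#' combinations (C1..C28) for a total of 29. With the default of 4 levels
#' per compound the multiplicative factors are `log_step^c(-2,-1,1,2)`,
#' placing the reference interior to each gradient.
#'
#' @param base Named compound mix for the reference combination
#'   (default [m63_mix()]).
#' @param levels_per_compound Named integer vector giving the number of
#'   gradient levels for each compound; must sum to 28. Default 4 per
#'   compound.
#' @param log_step Multiplicative step of the gradient (> 1), default 10.
#' @return An object of class `nichespan_design`: a list with
#'   `combinations` (list of 29, each with `id`, `mix`, `ions`,
#'   `varied_compound`, `factor`), `reference_id` (`"C0"`), and the base
#'   mix.
#' @export
build_design_matrix <- function(base = m63_mix(),
                                levels_per_compound = NULL,
                                log_step = 10) {
  base <- as_compound_mix(base)
  if (!is.numeric(log_step) || length(log_step) != 1 || log_step <= 1) {
    stop("log_step must be a single number > 1")
  }
  if (is.null(levels_per_compound)) {
    levels_per_compound <- stats::setNames(rep(4L, 7), compound_names())
  }
  unknown <- setdiff(names(levels_per_compound), compound_names())
  if (length(unknown) > 0) {
    stop("levels_per_compound names unknown: ", paste(unknown, collapse = ", "))
  }
  lv <- stats::setNames(integer(7), compound_names())
  lv[names(levels_per_compound)] <- as.integer(levels_per_compound)
  if (any(lv < 0)) stop("levels must be non-negative")
  if (sum(lv) != 28L) {
    stop("levels_per_compound must sum to 28 variants (got ", sum(lv), ")")
  }
  combos <- list(list(id = "C0", mix = base, ions = compound_to_ions(base),
                      varied_compound = NA_character_, factor = 1))
  idx <- 0L
  for (cmp in compound_names()) {
    n <- lv[[cmp]]
    if (n == 0L) next
    if (base[[cmp]] <= 0) {
      stop("cannot build a multiplicative gradient on '", cmp,
           "': base concentration is zero")
    }
    exps <- setdiff(seq(-ceiling(n / 2), floor(n / 2)), 0L)
    for (e in exps) {
      idx <- idx + 1L
      mix <- base
      mix[[cmp]] <- base[[cmp]] * log_step^e
      combos[[length(combos) + 1L]] <- list(
        id = paste0("C", idx), mix = mix, ions = compound_to_ions(mix),
        varied_compound = cmp, factor = log_step^e)
    }
  }
  structure(list(combinations = combos, reference_id = "C0", base = base,
                 log_step = log_step),
            class = "nichespan_design")
}

#' @export
print.nichespan_design <- function(x, ...) {
  cat("Medium design:", length(x$combinations), "combinations,",
      length(constituent_names()), "constituents; reference",
      x$reference_id, "\n")
  invisible(x)
}

#' Tabulate a design matrix
#'
#' `design_ions_table()` returns the long table of ionic constituent
#' concentrations (combination_id, constituent, mol_per_L);
#' `design_compounds_table()` the compound-level companion
#' (combination_id, compound, mol_per_L, varied).
#'
#' @param design A `nichespan_design`.
#' @return A data.frame.
#' @export
design_ions_table <- function(design) {
  stopifnot(inherits(design, "nichespan_design"))
  rows <- lapply(design$combinations, function(cb) {
    data.frame(combination_id = cb$id,
               constituent = constituent_names(),
               mol_per_L = unname(cb$ions[constituent_names()]))
  })
  do.call(rbind, rows)
}

#' @rdname design_ions_table
#' @export
design_compounds_table <- function(design) {
  stopifnot(inherits(design, "nichespan_design"))
  rows <- lapply(design$combinations, function(cb) {
    data.frame(combination_id = cb$id,
               compound = compound_names(),
               mol_per_L = unname(cb$mix[compound_names()]),
               varied = compound_names() %in% cb$varied_compound)
  })
  do.call(rbind, rows)
}

# Lookup a combination by id.
design_combo <- function(design, id) {
  ids <- vapply(design$combinations, `[[`, character(1), "id")
  i <- match(id, ids)
  if (is.na(i)) stop("unknown combination id: ", id)
  design$combinations[[i]]
}

# Which constituents does a combination's varied compound contribute to?
varied_constituents <- function(combo) {
  if (is.na(combo$varied_compound)) return(character(0))
  s <- stoichiometry_matrix()
  rownames(s)[s[, combo$varied_compound] > 0]
}
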