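# Singly charged ion species for positive-mode ESI annotation.
#
# Every species is modeled on a protonated frame: [nM + sum(deltas) + H]+
# where each delta is a small composable atom change (metal/H replacement,
# ammonia adduction, neutral loss). The proton carries the +1 charge and the
# electron bookkeeping, so the mass offset of [M+H]+ is H - e = 1.007276 Da
# and, e.g., [M+Na]+ = proton + (Na - H) = Na - e, reproducing printed
# adduct m/z values to 4 decimals.

# Base deltas: net atom change applied to the protonated frame.
.BASE_DELTAS <- list(
  Na_adduct  = c(Na = 1, H = -1),  # labile H replaced by Na
  K_adduct   = c(K = 1, H = -1),
  Ca_adduct  = c(Ca = 1, H = -2),  # Ca2+ replaces two labile protons
  NH3_adduct = c(N = 1, H = 3),    # [M+H]+ -> [M+NH4]+
  H2O_loss   = c(O = -1, H = -2),
  NH3_loss   = c(N = -1, H = -3)
)

#' Names of the available base mass deltas
#'
#' @return Character vector of delta names usable in annotation sets:
#'   `"Na_adduct"`, `"K_adduct"`, `"Ca_adduct"`, `"NH3_adduct"`,
#'   `"H2O_loss"`, `"NH3_loss"`.
#' @export
base_delta_names <- function() names(.BASE_DELTAS)

# Mass of one base delta, computed from the element table (never hard-coded).
delta_mass <- function(name) {
  d <- .BASE_DELTAS[[name]]
  if (is.null(d)) stop(sprintf("unknown base delta '%s'", name))
  sum(.ELEMENT_MASSES[names(d)] * d)
}

# Net atom change of a species' deltas (named integer vector, may be empty).
net_atom_change <- function(counts) {
  net <- integer(0)
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (k == 0) next
    d <- .BASE_DELTAS[[nm]] * k
    for (el in names(d)) net[el] <- (if (el %in% names(net)) net[el] else 0L) + d[[el]]
  }
  net[net != 0]
}

#' Construct an ion species
#'
#' An ion species is a singly charged positive ion form `[nM +/- ...]+`:
#' `n` copies of the neutral molecule, a proton charge carrier, and any
#' number of base deltas (metal/H replacements, ammonia adduction, neutral
#' losses). Net charge is +1 by construction.
#'
#' @param multimer_n Positive integer: 1 = monomer, 2 = dimer, 3 = trimer...
#' @param deltas Named integer vector of base-delta application counts,
#'   e.g. `c(Na_adduct = 2)` for `[M+2Na-H]+`; empty for `[nM+H]+`.
#' @return An `ion_species` object with fields `multimer_n`, `deltas`,
#'   `offset` (mass offset in Da, see [mass_offset()]) and `label`.
#' @examples
#' ion_species(1, c(Na_adduct = 1))           # [M+Na]+
#' ion_species(2)                             # [2M+H]+
#' ion_species(3, c(Ca_adduct = 1))           # [3M+Ca-H]+
#' @export
ion_species <- function(multimer_n = 1L, deltas = integer(0)) {
  multimer_n <- as.integer(multimer_n)
  if (is.na(multimer_n) || multimer_n < 1L)
    stop("multimer_n must be a positive integer")
  if (length(deltas)) {
    bad <- setdiff(names(deltas), names(.BASE_DELTAS))
    if (length(bad)) stop(sprintf("unknown base delta '%s'", bad[1]))
    deltas <- deltas[deltas != 0]
  }
  counts <- vapply(names(.BASE_DELTAS), function(nm)
    if (nm %in% names(deltas)) as.integer(deltas[[nm]]) else 0L, integer(1))
  offset <- .PROTON_MASS + sum(vapply(names(.BASE_DELTAS), function(nm)
    counts[[nm]] * delta_mass(nm), numeric(1)))
  s <- structure(list(multimer_n = multimer_n, deltas = counts, offset = offset),
                 class = "ion_species")
  s$label <- species_label(s)
  s
}

#' Mass offset of an ion species
#'
#' The offset `o` such that the observed m/z of the species for a neutral
#' monoisotopic mass M is `n * M + o`. Includes the proton (H minus one
#' electron) and all delta masses, computed from the element table.
#'
#' @param species An [ion_species()].
#' @return Offset in Da.
#' @export
mass_offset <- function(species) {
  stopifnot(inherits(species, "ion_species"))
  species$offset
}

#' m/z of an ion species for a given neutral mass
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da (positive).
#' @param species An [ion_species()] (net charge +1).
#' @return m/z = `multimer_n * neutral_mass + mass_offset(species)`.
#' @examples
#' ion_mz(monoisotopic_mass("C5H9NO2"), ion_species(1, c(K_adduct = 1)))
#' # proline [M+K]+ = 154.0265
#' @export
ion_mz <- function(neutral_mass, species) {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("neutral_mass must be positive")
  if (!inherits(species, "ion_species"))
    stop("species must be an ion_species (singly charged positive)")
  species$multimer_n * neutral_mass + species$offset
}

#' Mass delta between two species of the same multimer order
#'
#' @param a,b [ion_species()] objects with equal `multimer_n`.
#' @return `mass_offset(b) - mass_offset(a)` in Da. Deltas across multimer
#'   orders depend on the neutral mass and are an error here; multimer
#'   relations are handled by the graph builder.
#' @examples
#' species_delta(ion_species(1), ion_species(1, c(Na_adduct = 1))) # 21.9819
#' @export
species_delta <- function(a, b) {
  stopifnot(inherits(a, "ion_species"), inherits(b, "ion_species"))
  if (a$multimer_n != b$multimer_n)
    stop("species_delta is undefined across multimer orders; use the graph builder's multimer matching")
  b$offset - a$offset
}

# Canonical bracket label. Additions sorted Na < K < Ca < NH4/NH3; the
# charge-carrier hydrogen is folded into NH4 when an ammonia gain is present
# and a free proton remains; losses come last.
species_label <- function(s) {
  d <- s$deltas
  n_na <- d[["Na_adduct"]]; n_k <- d[["K_adduct"]]; n_ca <- d[["Ca_adduct"]]
  n_nh3g <- d[["NH3_adduct"]]; n_h2o <- d[["H2O_loss"]]; n_nh3l <- d[["NH3_loss"]]
  hydro <- 1L - n_na - n_k - 2L * n_ca
  n_nh4 <- 0L
  if (n_nh3g > 0L && hydro > 0L) { n_nh4 <- 1L; n_nh3g <- n_nh3g - 1L; hydro <- hydro - 1L }
  piece <- function(k, sym) if (k > 0L) sprintf("+%s%s", if (k > 1L) k else "", sym) else ""
  parts <- paste0(
    piece(n_na, "Na"), piece(n_k, "K"), piece(n_ca, "Ca"),
    piece(n_nh4, "NH4"), piece(n_nh3g, "NH3"),
    if (hydro > 0L) piece(hydro, "H") else "",
    if (hydro < 0L) sprintf("-%sH", if (-hydro > 1L) -hydro else "") else "",
    if (n_h2o > 0L) sprintf("-%sH2O", if (n_h2o > 1L) n_h2o else "") else "",
    if (n_nh3l > 0L) sprintf("-%sNH3", if (n_nh3l > 1L) n_nh3l else "") else ""
  )
  sprintf("[%sM%s]+", if (s$multimer_n > 1L) s$multimer_n else "", parts)
}

#' Parse a canonical species label
#'
#' Inverse of the label generator: `parse_species_label(s$label)` returns a
#' species with the same multimer order and mass offset.
#'
#' @param label Bracket notation such as `"[2M+Na]+"` or `"[M+2Na-H]+"`.
#' @return An [ion_species()].
#' @export
parse_species_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^\\[([0-9]*)M((?:[+-][0-9]*(?:Na|K|Ca|NH4|NH3|H2O|H))*)\\]\\+$",
                                 label))[[1]]
  if (length(m) == 0 || !nzchar(m[1]))
    stop(sprintf("cannot parse species label '%s'", label))
  n <- if (nzchar(m[2])) as.integer(m[2]) else 1L
  body <- m[3]
  toks <- regmatches(body, gregexpr("[+-][0-9]*(?:Na|K|Ca|NH4|NH3|H2O|H)", body))[[1]]
  deltas <- c(Na_adduct = 0L, K_adduct = 0L, Ca_adduct = 0L,
              NH3_adduct = 0L, H2O_loss = 0L, NH3_loss = 0L)
  for (t in toks) {
    sign <- if (substr(t, 1, 1) == "+") 1L else -1L
    rest <- substring(t, 2)
    cnt <- sub("^([0-9]*).*$", "\\1", rest)
    k <- if (nzchar(cnt)) as.integer(cnt) else 1L
    sym <- sub("^[0-9]*", "", rest)
    switch(sym,
      Na = { if (sign < 0) stop("sodium loss is not a supported species"); deltas["Na_adduct"] <- deltas["Na_adduct"] + k },
      K  = { if (sign < 0) stop("potassium loss is not a supported species"); deltas["K_adduct"] <- deltas["K_adduct"] + k },
      Ca = { if (sign < 0) stop("calcium loss is not a supported species"); deltas["Ca_adduct"] <- deltas["Ca_adduct"] + k },
      NH4 = { if (sign < 0) stop("NH4 loss is not a supported species"); deltas["NH3_adduct"] <- deltas["NH3_adduct"] + k },
      NH3 = { if (sign > 0) deltas["NH3_adduct"] <- deltas["NH3_adduct"] + k else deltas["NH3_loss"] <- deltas["NH3_loss"] + k },
      H2O = { if (sign > 0) stop("water gain is not a supported species"); deltas["H2O_loss"] <- deltas["H2O_loss"] + k },
      H  = NULL
    )
  }
  # hydrogen balance is implied by the replacements; verify the label's
  # explicit H terms agree, otherwise the species is not singly charged
  d <- deltas
  expected_h_term <- 1L - d[["Na_adduct"]] - d[["K_adduct"]] - 2L * d[["Ca_adduct"]]
  # NH4 in the label consumes one free proton
  has_nh4 <- grepl("NH4", body, fixed = TRUE)
  if (has_nh4) expected_h_term <- expected_h_term - 1L
  h_toks <- regmatches(body, gregexpr("[+-][0-9]*H(?!2)", body, perl = TRUE))[[1]]
  h_term <- 0L
  for (t in h_toks) {
    k <- sub("^[+-]([0-9]*)H$", "\\1", t)
    k <- if (nzchar(k)) as.integer(k) else 1L
    h_term <- h_term + (if (substr(t, 1, 1) == "+") k else -k)
  }
  if (h_term != expected_h_term)
    stop(sprintf("label '%s' is not a valid singly charged species (hydrogen balance)", label))
  ion_species(n, deltas)
}

#' @export
format.ion_species <- function(x, ...) x$label

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion species> %s  offset %+0.4f Da (n = %d)\n",
              x$label, x$offset, x$multimer_n))
  invisible(x)
}

#' Expand the species closure of an annotation set
#'
#' Enumerates every distinct ion species reachable by applying at most
#' `max_depth` base deltas (with repetition, so replacement series like
#' `[M+nNa-(n-1)H]+` arise) to the protonated frame `[nM+H]+`, for each
#' multimer order. Combinations with identical net atom composition are
#' merged, keeping the shortest derivation.
#'
#' @param base_deltas Character vector of base delta names
#'   (see [base_delta_names()]).
#' @param max_depth Maximum number of base deltas combined (default 3).
#' @param multimers Integer vector of multimer orders (default `1:3`,
#'   i.e. monomers, dimers and trimers).
#' @param max_losses Maximum number of neutral-loss steps (water, ammonia)
#'   allowed inside one combined species (default 1). Chains of different
#'   neutral losses produce many low-m/z windows and exact compositional
#'   coincidences between unrelated metabolites (losing 2 NH3 + H2O from
#'   homocitrulline gives exactly trigonelline's composition), so they are
#'   excluded from the default closure; raise the budget to explore deeper
#'   loss chains.
#' @return List of [ion_species()], sorted by multimer order then offset.
#' @examples
#' cl <- expand_species_closure("Na_adduct", max_depth = 3, multimers = 1)
#' vapply(cl, function(s) s$label, "") # the [M+nNa-(n-1)H]+ series
#' @export
expand_species_closure <- function(base_deltas = c("NH3_adduct", "Na_adduct", "K_adduct",
                                                   "H2O_loss", "NH3_loss"),
                                   max_depth = 3L, multimers = 1:3,
                                   max_losses = 1L) {
  if (max_depth < 1L) stop("max_depth must be >= 1")
  bad <- setdiff(base_deltas, names(.BASE_DELTAS))
  if (length(bad)) stop(sprintf("unknown base delta '%s'", bad[1]))
  multimers <- sort(unique(as.integer(multimers)))
  if (any(multimers < 1L)) stop("multimer orders must be positive")

  # multisets of base deltas of size 0..max_depth within the loss budget
  loss_names <- c("H2O_loss", "NH3_loss")
  combos <- list(integer(0))
  frontier <- list(integer(0))
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (cmb in frontier) {
      for (b in base_deltas) {
        new <- cmb
        new[b] <- (if (b %in% names(new)) new[[b]] else 0L) + 1L
        if (sum(new[names(new) %in% loss_names]) > max_losses) next
        nxt[[paste(names(new)[order(names(new))],
                   new[order(names(new))], collapse = ";")]] <- new
      }
    }
    frontier <- nxt
    combos <- c(combos, unname(nxt))
  }

  out <- list()
  for (n in multimers) {
    seen <- character(0)
    for (cmb in combos) {
      s <- ion_species(n, cmb)
      key <- {
        net <- net_atom_change(s$deltas)
        if (length(net)) {
          o <- order(names(net))
          paste(names(net)[o], net[o], collapse = ";")
        } else ""
      }
      if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1L]] <- s }
    }
  }
  ord <- order(vapply(out, function(s) s$multimer_n, integer(1)),
               vapply(out, function(s) s$offset, numeric(1)))
  out[ord]
}

# TRUE when an edge matched by this species is directionally ambiguous:
# a +17.0265 shift between two monomer peaks can be read as [M+H]+ ->
# [M+NH4]+ (adduct) or, reversed, as a loss of NH3.
species_is_ambiguous <- function(s) {
  d <- s$deltas
  s$multimer_n == 1L &&
    ((d[["NH3_adduct"]] == 1L && sum(d) == 1L) ||
     (d[["NH3_loss"]] == 1L && sum(d) == 1L))
}
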