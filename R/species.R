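# Species enumeration and the declarative reaction list.
#
# A receptor carries three binary states: ligand bound, dimerized (lumped with
# autophosphorylation), reporter bound. Closing that state space under mass
# action gives exactly 16 species: free ligand, free reporter, 4 monomer
# states and 10 dimer states resolved at the protomer level (each protomer is
# one of: empty "o", liganded "l", reporter-bound "z", both "lz").
# Reporter ASSOCIATION is restricted to ligand-bound (hence phosphorylated)
# dimers; reporter-carrying species without ligand (N13-N16) arise only
# transiently from ligand or dimer dissociation, because no dephosphorylation
# step is modeled and bound reporter is released only at rate k4.

.speciesTable <- function() {
  # protomers: "" for non-dimer species
  tab <- data.frame(
    label = paste0("N", 1:16),
    description = c(
      "free ligand (clamped)",
      "free cytosolic tSH2 reporter",
      "receptor monomer",
      "ligand-bound receptor monomer",
      "ligand-free (pre-formed) dimer",
      "dimer, one ligand",
      "dimer, two ligands",
      "dimer, one ligand + reporter on the liganded protomer",
      "dimer, two ligands, one reporter",
      "dimer, two ligands, two reporters",
      "dimer, one ligand, reporter on the unliganded protomer",
      "dimer, one ligand, two reporters",
      "dimer, no ligand, one reporter (post-dissociation)",
      "dimer, no ligand, two reporters (post-dissociation)",
      "monomer with bound reporter (post-dissociation)",
      "ligand-bound monomer with bound reporter (post-dissociation)"
    ),
    protomers = c("", "", "", "", "o.o", "l.o", "l.l", "lz.o", "lz.l",
                  "lz.lz", "l.z", "lz.z", "z.o", "z.z", "", ""),
    receptor_count  = c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L),
    ligand_occupancy   = c(0L, 0L, 0L, 1L, 0L, 1L, 2L, 1L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 1L),
    reporter_occupancy = c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L),
    is_dimer        = c(rep(FALSE, 4), rep(TRUE, 10), FALSE, FALSE),
    is_free_ligand  = c(TRUE, rep(FALSE, 15)),
    is_free_reporter = c(FALSE, TRUE, rep(FALSE, 14)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$label
  tab
}

.reactionList <- function() {
  rxn <- function(rate, mult, reactants, products)
    list(rate = rate, mult = mult, reactants = reactants, products = products)
  c(
    # --- ligand association (k1, per free binding site; ligand clamped)
    list(
      rxn("k1", 1, c("N1", "N3"),  "N4"),
      rxn("k1", 1, c("N1", "N15"), "N16"),
      rxn("k1", 2, c("N1", "N5"),  "N6"),
      rxn("k1", 1, c("N1", "N6"),  "N7"),
      rxn("k1", 1, c("N1", "N13"), "N11"),  # onto the empty protomer
      rxn("k1", 1, c("N1", "N13"), "N8"),   # onto the reporter-bound protomer
      rxn("k1", 2, c("N1", "N14"), "N12"),
      rxn("k1", 1, c("N1", "N8"),  "N9"),
      rxn("k1", 1, c("N1", "N11"), "N9"),
      rxn("k1", 1, c("N1", "N12"), "N10")
    ),
    # --- ligand dissociation (k7, beta-scaled, per bound ligand)
    list(
      rxn("k7", 1, "N4",  c("N3", "N1")),
      rxn("k7", 1, "N16", c("N15", "N1")),
      rxn("k7", 1, "N6",  c("N5", "N1")),
      rxn("k7", 2, "N7",  c("N6", "N1")),
      rxn("k7", 1, "N8",  c("N13", "N1")),
      rxn("k7", 1, "N11", c("N13", "N1")),
      rxn("k7", 1, "N9",  c("N8", "N1")),   # from the plain-liganded protomer
      rxn("k7", 1, "N9",  c("N11", "N1")),  # from the liganded+reporter protomer
      rxn("k7", 2, "N10", c("N12", "N1")),
      rxn("k7", 1, "N12", c("N14", "N1"))
    ),
    # --- dimerization (k5, lumped with autophosphorylation).
    # Convention: d[D]/dt = k5*[X]^2 for identical partners, with the
    # statistical factor 2 for distinct partners; this is the unique
    # convention under which the analytic pre-stimulus dimer equilibrium
    # N5 = (k5/k6) N3^2 is an exact fixed point.
    list(
      rxn("k5", 1, c("N3", "N3"),   "N5"),
      rxn("k5", 2, c("N3", "N4"),   "N6"),
      rxn("k5", 1, c("N4", "N4"),   "N7"),
      rxn("k5", 2, c("N3", "N16"),  "N8"),
      rxn("k5", 2, c("N4", "N16"),  "N9"),
      rxn("k5", 1, c("N16", "N16"), "N10"),
      rxn("k5", 2, c("N4", "N15"),  "N11"),
      rxn("k5", 2, c("N15", "N16"), "N12"),
      rxn("k5", 2, c("N3", "N15"),  "N13"),
      rxn("k5", 1, c("N15", "N15"), "N14")
    ),
    # --- dimer dissociation: k6 for ligand-free dimers, k3 (gamma-scaled)
    # for ligand-bound dimers
    list(
      rxn("k6", 1, "N5",  c("N3", "N3")),
      rxn("k6", 1, "N13", c("N3", "N15")),
      rxn("k6", 1, "N14", c("N15", "N15")),
      rxn("k3", 1, "N6",  c("N3", "N4")),
      rxn("k3", 1, "N7",  c("N4", "N4")),
      rxn("k3", 1, "N8",  c("N3", "N16")),
      rxn("k3", 1, "N9",  c("N4", "N16")),
      rxn("k3", 1, "N10", c("N16", "N16")),
      rxn("k3", 1, "N11", c("N4", "N15")),
      rxn("k3", 1, "N12", c("N15", "N16"))
    ),
    # --- reporter association (k2): only to free tails of dimers carrying
    # at least one ligand (phosphorylated, activated complexes)
    list(
      rxn("k2", 1, c("N2", "N6"),  "N8"),
      rxn("k2", 1, c("N2", "N6"),  "N11"),
      rxn("k2", 2, c("N2", "N7"),  "N9"),
      rxn("k2", 1, c("N2", "N8"),  "N12"),
      rxn("k2", 1, c("N2", "N9"),  "N10"),
      rxn("k2", 1, c("N2", "N11"), "N12")
    ),
    # --- reporter dissociation (k4, per bound reporter, from any species)
    list(
      rxn("k4", 1, "N8",  c("N6", "N2")),
      rxn("k4", 1, "N9",  c("N7", "N2")),
      rxn("k4", 2, "N10", c("N9", "N2")),
      rxn("k4", 1, "N11", c("N6", "N2")),
      rxn("k4", 1, "N12", c("N8", "N2")),   # off the reporter-only protomer
      rxn("k4", 1, "N12", c("N11", "N2")),  # off the liganded protomer
      rxn("k4", 1, "N13", c("N5", "N2")),
      rxn("k4", 2, "N14", c("N13", "N2")),
      rxn("k4", 1, "N15", c("N3", "N2")),
      rxn("k4", 1, "N16", c("N4", "N2"))
    )
  )
}

#' Enumerate the 16 species of the activation network
#'
#' Returns the ordered species catalogue with structural annotations:
#' receptor count per complex, ligand and reporter occupancy, dimer flag,
#' and free-ligand/free-reporter flags. N1 is the (clamped) free ligand,
#' N2 the free cytosolic reporter, N3 the receptor monomer, N4 the
#' ligand-bound monomer and N5 the ligand-free pre-formed dimer; N4 and
#' N6-N16 are the ligand- and/or reporter-bound species that are zero
#' before stimulation.
#'
#' @return a data.frame with one row per species, rownames N1..N16.
#' @examples
#' idx <- speciesIndex()
#' idx["N5", ]   # the ligand-free dimer
#' @export
speciesIndex <- function() .speciesTable()

#' Build the declarative reaction network
#'
#' Assembles the species catalogue, the elementary reaction list (rate
#' constant name, statistical multiplicity, reactants) and the stoichiometry
#' matrix used to generate the mass-action right-hand side. The free-ligand
#' row of the stoichiometry matrix is identically zero because ligand is in
#' vast excess and held constant.
#'
#' @return a [ReactionNetwork-class] object.
#' @examples
#' net <- reactionNetwork()
#' nrow(reactions(net))
#' @export
reactionNetwork <- function() {
  sp <- .speciesTable()
  rl <- .reactionList()
  n <- length(rl)
  S <- matrix(0L, nrow = 16L, ncol = n,
              dimnames = list(sp$label, NULL))
  r1 <- integer(n); r2 <- integer(n)
  rate <- character(n); mult <- numeric(n)
  lab <- character(n)
  for (j in seq_len(n)) {
    rx <- rl[[j]]
    rate[j] <- rx$rate
    mult[j] <- rx$mult
    ri <- match(rx$reactants, sp$label)
    pi <- match(rx$products, sp$label)
    stopifnot(!anyNA(ri), !anyNA(pi))
    r1[j] <- ri[1]
    r2[j] <- if (length(ri) > 1L) ri[2] else NA_integer_
    for (i in ri) S[i, j] <- S[i, j] - 1L
    for (i in pi) S[i, j] <- S[i, j] + 1L
    lab[j] <- paste0(paste(rx$reactants, collapse = " + "), " -> ",
                     paste(rx$products, collapse = " + "))
  }
  S[1L, ] <- 0L  # ligand clamped
  rxns <- data.frame(reaction = lab, rate = rate, multiplicity = mult,
                     r1 = r1, r2 = r2, stringsAsFactors = FALSE)
  new("ReactionNetwork", species = sp, reactions = rxns, stoichiometry = S)
}

#' @describeIn reactionNetwork species table accessor
#' @param object,x a ReactionNetwork
#' @export
species <- function(x) x@species

#' @describeIn reactionNetwork reaction table accessor
#' @export
reactions <- function(x) x@reactions

#' @describeIn reactionNetwork stoichiometry matrix accessor
#' @export
stoichiometry <- function(x) x@stoichiometry

#' Export the species and reaction tables as delimited text
#'
#' Writes two tab-separated files, `<prefix>_species.tsv` and
#' `<prefix>_reactions.tsv`, for inspection outside R.
#'
#' @param network a [ReactionNetwork-class].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
exportReactionTable <- function(network, prefix) {
  stopifnot(is(network, "ReactionNetwork"))
  fs <- paste0(prefix, c("_species.tsv", "_reactions.tsv"))
  write.table(network@species, fs[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network@reactions, fs[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fs)
}

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", nrow(object@species), "species,",
      nrow(object@reactions), "elementary reactions\n")
  cat("  dimers:", sum(object@species$is_dimer),
      "| clamped free ligand: N1 | free reporter: N2\n")
})
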