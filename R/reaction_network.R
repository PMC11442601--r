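#' @importFrom utils read.delim write.table
NULL

# Parse one side of a reaction equation, e.g. "2 HO. + H2O2" ->
# c("HO." = 2, "H2O2" = 1). Terms are separated by " + " (plus with
# surrounding whitespace) so species ids may themselves contain "+",
# "-", "." or "*" (H+, O2.-, 3RCOR*).
parse_stoich_side <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "" || x == ".") return(numeric(0))
  terms <- trimws(strsplit(x, "\\s\\+\\s|\\s\\+$|^\\+\\s")[[1]])
  terms <- terms[terms != ""]
  out <- numeric(0)
  for (term in terms) {
    m <- regmatches(term, regexec("^([0-9]+)\\s+(.+)$", term))[[1]]
    if (length(m) == 3) {
      coef <- as.numeric(m[2]); sp <- m[3]
    } else {
      coef <- 1; sp <- term
    }
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + coef
  }
  out
}

format_stoich_side <- function(s) {
  if (length(s) == 0) return("")
  paste(ifelse(s == 1, names(s), paste(s, names(s))), collapse = " + ")
}

parse_composition <- function(x) {
  if (is.na(x) || x == "") return(NULL)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                  vapply(kv, `[`, "", 1))
}

#' Default species registry
#'
#' Reads the shipped species table: id, display formula, charge, elemental
#' composition, macromolecule/excited-state flags, fixed (buffered) status
#' and an aqueous diffusion coefficient used for inter-compartment
#' exchange. Macromolecular species (the protein and its radicals, the
#' enzymes) carry no elemental composition and are exempt from element
#' balance checks. The free electron `e-` is a bookkeeping pseudo-species
#' for electrode reactions, never a state variable.
#'
#' @param path Optional path to an alternative species TSV with the same
#'   columns.
#' @return data.frame of species with parsed `composition` list-column.
#' @export
pef_species <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "species_default.tsv", package = "pefros",
                        mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(composition = "character"))
  df$composition <- lapply(df$composition, parse_composition)
  df
}

#' Load and validate a reaction network
#'
#' Reads a delimited reaction-definition table (columns `id`, `reactants`,
#' `products`, `k`, `k_units`, `kind`, `band_nm`, `provenance`; side syntax
#' `"2 HO. + H2O2"` with explicit integer coefficients) and returns a
#' validated network. The shipped default encodes the full
#' anodic/bulk/enzymatic/Fenton/cathodic scheme of PEF-driven ROS
#' chemistry in a buffered protein solution: 29 labelled reactions
#' (the hydroxyl-radical disproportionation/recombination pair counted as
#' two, `5a`/`5b`).
#'
#' Validation enforces: unique reaction ids; every referenced species
#' registered; non-negative rate constants; charge balance for every
#' reaction (the transferred electron `e-` counts as charge -1); element
#' balance for every reaction whose species all carry elemental
#' compositions (macromolecular species are exempt).
#'
#' The hydroperoxyl/superoxide acid-base pair is, by default, not a
#' kinetic reaction: it is treated as an instantaneous equilibrium at the
#' buffered pH (pKa 4.8, giving ~0.4 % HO2. at pH 7.2), repartitioned
#' continuously during simulation. `superoxide_mode = "explicit"` instead
#' adds explicit deprotonation/protonation reactions `11a`/`11b` derived
#' from the same pKa.
#'
#' @param reaction_table Path to a reaction TSV; default = shipped table.
#' @param species Species registry as returned by [pef_species()].
#' @param pH Buffered pH (fixed; phosphate-buffered experiments run at 7.2).
#' @param superoxide_mode `"equilibrium"` (default) or `"explicit"`.
#' @param pKa_superoxide Acid dissociation constant of HO2., default 4.8.
#' @param k_overrides Optional named numeric vector of rate-constant
#'   overrides keyed by reaction id, e.g. `c("12" = 1e4)` for a
#'   metal-catalysed Haber-Weiss constant.
#' @return Object of class `pef_network`.
#' @export
#' @examples
#' net <- load_network()
#' net
load_network <- function(reaction_table = NULL,
                         species = pef_species(),
                         pH = 7.2,
                         superoxide_mode = c("equilibrium", "explicit"),
                         pKa_superoxide = 4.8,
                         k_overrides = NULL) {
  superoxide_mode <- match.arg(superoxide_mode)
  if (is.null(reaction_table))
    reaction_table <- system.file("extdata", "reactions_default.tsv",
                                  package = "pefros", mustWork = TRUE)
  rx <- read.delim(reaction_table, stringsAsFactors = FALSE,
                   colClasses = c(id = "character"))
  required <- c("id", "reactants", "products", "k", "k_units", "kind",
                "provenance")
  if (!all(required %in% names(rx)))
    stop("reaction table schema error: missing column(s) ",
         paste(setdiff(required, names(rx)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(rx$id))
    stop("duplicate reaction id(s): ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(k_overrides)) {
    unknown <- setdiff(names(k_overrides), rx$id)
    if (length(unknown))
      stop("k_overrides for unknown reaction id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    rx$k[match(names(k_overrides), rx$id)] <- unname(k_overrides)
  }
  if (any(!is.finite(rx$k) | rx$k < 0))
    stop("rate constants must be finite and >= 0", call. = FALSE)

  if (superoxide_mode == "explicit") {
    # forward deprotonation k_f and reprotonation k_b * [H+] chosen so that
    # k_f / (k_b) = Ka with a diffusion-limited reprotonation constant
    k_b <- 5e10                       # M-1 s-1, H+ + O2.- recombination
    k_f <- k_b * 10^(-pKa_superoxide) # s-1
    rx <- rbind(rx,
      data.frame(id = c("11a", "11b"),
                 reactants = c("HO2.", "O2.- + H+"),
                 products = c("O2.- + H+", "HO2."),
                 k = c(k_f, k_b), k_units = c("s-1", "M-1 s-1"),
                 kind = "bulk", band_nm = NA,
                 provenance = "acid-base kinetics generated from pKa 4.8",
                 stringsAsFactors = FALSE))
  }

  reac <- lapply(rx$reactants, parse_stoich_side)
  prod <- lapply(rx$products, parse_stoich_side)
  all_sp <- unique(c(unlist(lapply(reac, names)), unlist(lapply(prod, names))))
  unknown <- setdiff(all_sp, species$id)
  if (length(unknown))
    stop("schema error: unknown species ", paste(unknown, collapse = ", "),
         call. = FALSE)

  charge <- stats::setNames(species$charge, species$id)
  comp <- stats::setNames(species$composition, species$id)
  macro <- stats::setNames(species$macromolecule, species$id)
  for (i in seq_len(nrow(rx))) {
    r <- reac[[i]]; p <- prod[[i]]
    dq <- sum(charge[names(p)] * p) - sum(charge[names(r)] * r)
    if (length(r) == 0 && length(p) == 0)
      stop("reaction ", rx$id[i], " has empty reactant and product sides",
           call. = FALSE)
    if (abs(dq) > 1e-9)
      stop("charge balance error in reaction ", rx$id[i],
           " (net charge change ", dq, ")", call. = FALSE)
    sps <- c(names(r), names(p))
    if (!any(macro[sps])) {
      elem <- new.env()
      add <- function(side, sign) {
        for (s in names(side)) {
          cc <- comp[[s]]
          for (el in names(cc)) {
            cur <- if (!is.null(elem[[el]])) elem[[el]] else 0
            elem[[el]] <- cur + sign * side[[s]] * cc[[el]]
          }
        }
      }
      add(r, 1); add(p, -1)
      bad <- Filter(function(el) abs(elem[[el]]) > 1e-9, ls(elem))
      if (length(bad))
        stop("balance error in reaction ", rx$id[i], ": element(s) ",
             paste(bad, collapse = ", "), " not conserved", call. = FALSE)
    }
  }

  # electrons transferred per event (from the e- pseudo-species)
  z <- vapply(seq_len(nrow(rx)), function(i) {
    ze <- 0
    if ("e-" %in% names(prod[[i]])) ze <- prod[[i]][["e-"]]
    if ("e-" %in% names(reac[[i]])) ze <- reac[[i]][["e-"]]
    ze
  }, 0)
  electrode <- rx$kind %in% c("anodic", "cathodic")
  if (any(electrode & z < 1))
    stop("electrode reaction(s) without transferred electron: ",
         paste(rx$id[electrode & z < 1], collapse = ", "), call. = FALSE)
  if (any(!electrode & z != 0))
    stop("non-electrode reaction(s) must not transfer electrons: ",
         paste(rx$id[!electrode & z != 0], collapse = ", "), call. = FALSE)

  rx$z <- z
  net <- structure(
    list(species = species, reactions = rx,
         reactant_stoich = reac, product_stoich = prod,
         pH = pH, pKa_superoxide = pKa_superoxide,
         superoxide_mode = superoxide_mode,
         fixed_species = species$id[species$fixed]),
    class = "pef_network")
  net
}

#' @export
print.pef_network <- function(x, ...) {
  kinds <- table(x$reactions$kind)
  cat(sprintf("ROS reaction network: %d species, %d reactions (%s)\n",
              sum(!x$species$fixed & x$species$id != "e-"),
              nrow(x$reactions),
              paste(sprintf("%s %d", names(kinds), kinds), collapse = ", ")))
  cat(sprintf("  buffered at pH %.1f; superoxide acid-base: %s (pKa %.1f)\n",
              x$pH, x$superoxide_mode, x$pKa_superoxide))
  invisible(x)
}

#' Fraction of the superoxide pool present as HO2. at the buffered pH
#'
#' @param network A `pef_network`.
#' @return Fraction in `[0, 1]`; ~0.004 at pH 7.2 with pKa 4.8.
#' @export
superoxide_protonated_fraction <- function(network) {
  1 / (1 + 10^(network$pH - network$pKa_superoxide))
}

#' State (dynamic) species of a network
#'
#' Species that evolve during simulation: everything except the buffered
#' fixed species and the electron pseudo-species.
#'
#' @param network A `pef_network`.
#' @return Character vector of species ids.
#' @export
state_species <- function(network) {
  sp <- network$species
  sp$id[!sp$fixed]
}

# Net stoichiometry matrix over state species (species x reactions),
# kinetic rows only unless all = TRUE.
network_stoichiometry <- function(network, all = FALSE) {
  sps <- state_species(network)
  keep <- if (all) seq_len(nrow(network$reactions)) else
    which(!network$reactions$kind %in% c("anodic", "cathodic"))
  S <- matrix(0, length(sps), length(keep),
              dimnames = list(sps, network$reactions$id[keep]))
  for (j in seq_along(keep)) {
    i <- keep[j]
    r <- network$reactant_stoich[[i]]; p <- network$product_stoich[[i]]
    for (s in names(r)) if (s %in% sps) S[s, j] <- S[s, j] - r[[s]]
    for (s in names(p)) if (s %in% sps) S[s, j] <- S[s, j] + p[[s]]
  }
  S
}

#' Mass-action rate of a single reaction
#'
#' rate = k * prod over reactants c_i^nu_i, with buffered (fixed) species
#' folded into the rate constant (unit activity) and enzymatic reactions
#' using the bimolecular `k * [enzyme] * [substrate]` form (linear in the
#' substrate: at the enzyme loadings modelled here substrate
#' concentrations are far below K_M, so no Michaelis saturation applies).
#'
#' @param network A `pef_network`.
#' @param reaction_id Reaction id (character, e.g. `"5b"`).
#' @param conc Named concentration vector (M), must cover the reaction's
#'   non-fixed reactants; all values must be >= 0.
#' @return Rate (M s^-1).
#' @export
#' @examples
#' net <- load_network()
#' mass_action_rate(net, "5b", c("HO." = 1e-9))  # 5.5e9 * (1e-9)^2
mass_action_rate <- function(network, reaction_id, conc) {
  i <- match(reaction_id, network$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  if (any(conc < 0))
    stop("state error: negative concentration(s)", call. = FALSE)
  kind <- network$reactions$kind[i]
  if (kind %in% c("anodic", "cathodic"))
    stop("electrode reaction rates are current-driven, not mass-action",
         call. = FALSE)
  r <- network$reactant_stoich[[i]]
  r <- r[!(names(r) %in% network$fixed_species)]
  rate <- network$reactions$k[i]
  for (s in names(r)) {
    cs <- if (s %in% names(conc)) conc[[s]] else 0
    expo <- if (kind == "enzymatic") 1 else r[[s]]
    rate <- rate * cs^expo
  }
  unname(rate)
}

# Precompiled kinetic structure for fast RHS evaluation: up to two
# distinct non-fixed reactants per row (the shipped scheme never needs
# more), exponents collapsed to index pairs.
compile_kinetics <- function(network) {
  sps <- state_species(network)
  keep <- which(!network$reactions$kind %in% c("anodic", "cathodic"))
  k <- network$reactions$k[keep]
  i1 <- i2 <- rep(NA_integer_, length(keep))
  for (j in seq_along(keep)) {
    r <- network$reactant_stoich[[keep[j]]]
    r <- r[!(names(r) %in% network$fixed_species)]
    if (network$reactions$kind[keep[j]] == "enzymatic") r[] <- 1
    idx <- rep(match(names(r), sps), times = r)
    if (length(idx) > 2)
      stop("kinetic reactions with more than two non-fixed reactant ",
           "molecules are not supported", call. = FALSE)
    if (length(idx) >= 1) i1[j] <- idx[1]
    if (length(idx) == 2) i2[j] <- idx[2]
  }
  list(S = network_stoichiometry(network), k = k, i1 = i1, i2 = i2,
       ids = network$reactions$id[keep],
       species = sps)
}

# Vectorised kinetic rates for one compartment given concentration vector
# in state_species order.
kinetic_rates <- function(kin, conc) {
  c1 <- ifelse(is.na(kin$i1), 1, conc[kin$i1])
  c2 <- ifelse(is.na(kin$i2), 1, conc[kin$i2])
  kin$k * c1 * c2
}

#' Write a trajectory to a delimited text file
#'
#' One time column, one column per species per compartment
#' (`species.compartment`), one column per emission band photon rate, and
#' the cumulative transferred charge.
#'
#' @param trajectory A `pef_trajectory` from [simulate_pef()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  conc <- trajectory$concentrations
  wide <- do.call(cbind, lapply(dimnames(conc)[[3]], function(comp) {
    m <- conc[, , comp, drop = FALSE][, , 1]
    colnames(m) <- paste(colnames(m), comp, sep = ".")
    m
  }))
  out <- data.frame(time_s = trajectory$time, wide,
                    check.names = FALSE)
  pr <- trajectory$photon_rate
  colnames(pr) <- paste0("photons_s.", colnames(pr))
  out <- cbind(out, pr, charge_C = trajectory$charge)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
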