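# Pathway construction and the parameter registry.
#
# Naming convention for registered parameters:
#   k_<ENZ>_<SUB>  catalytic turnover (kcat) of enzyme ENZ on substrate SUB
#   Km_<ENZ>_<SUB> Michaelis constant of ENZ on SUB
#   <ENZ>t         enzyme concentration (Et), shared by all reactions of ENZ
# Enzymes with a prime in their biochemical name use ASCII identifiers:
# F3pH = F3'H, F35pH = F3'5'H.

.SPECIES_FULL <- c("PCoA", "cha", "nar", "DHK", "DHQ", "DHM",
                   "LCP", "LCC", "LCD", "pel", "cya", "del",
                   "kam", "que", "myr")
.SPECIES_LINEAR <- c("PCoA", "cha", "nar", "DHK", "LCP", "pel")
.ANTHOCYANINS <- c("pel", "cya", "del")
.END_PRODUCTS <- c("pel", "cya", "del", "kam", "que", "myr")
.ENZYMES_FULL <- c("CHS", "CHI", "F3H", "F3pH", "F35pH", "DFR", "FLS", "ANS")
.ENZYMES_LINEAR <- c("CHS", "CHI", "F3H", "DFR", "ANS")

# canonical reaction table of the full topology (two-substrate F3'5'H)
.reactions_full <- function(f35ph_substrates = c("DHK", "DHQ")) {
  rx <- data.frame(
    enzyme    = c("CHS", "CHI", "F3H", "F3pH", "F35pH", "F35pH",
                  "DFR", "DFR", "DFR", "FLS", "FLS", "FLS",
                  "ANS", "ANS", "ANS"),
    substrate = c("PCoA", "cha", "nar", "DHK", "DHK", "DHQ",
                  "DHK", "DHQ", "DHM", "DHK", "DHQ", "DHM",
                  "LCP", "LCC", "LCD"),
    product   = c("cha", "nar", "DHK", "DHQ", "DHM", "DHM",
                  "LCP", "LCC", "LCD", "kam", "que", "myr",
                  "pel", "cya", "del"),
    stringsAsFactors = FALSE
  )
  drop <- rx$enzyme == "F35pH" & !(rx$substrate %in% f35ph_substrates)
  rx[!drop, , drop = FALSE]
}

.reactions_linear <- function() {
  data.frame(
    enzyme    = c("CHS", "CHI", "F3H", "DFR", "ANS"),
    substrate = c("PCoA", "cha", "nar", "DHK", "LCP"),
    product   = c("cha", "nar", "DHK", "LCP", "pel"),
    stringsAsFactors = FALSE
  )
}

.registry_names <- function(reactions) {
  kin <- c(rbind(paste0("k_", reactions$enzyme, "_", reactions$substrate),
                 paste0("Km_", reactions$enzyme, "_", reactions$substrate)))
  c(kin, paste0(unique(reactions$enzyme), "t"))
}

# enzyme an evolvable parameter belongs to, and whether it is regulatory (Et)
#' Map registered parameter names to their enzyme
#'
#' @param params character vector of registry names (`k_*`, `Km_*`, `<ENZ>t`).
#' @return character vector of enzyme identifiers.
#' @export
param_enzyme <- function(params) {
  ifelse(grepl("^(k|Km)_", params),
         sub("^(k|Km)_([^_]+)_.*$", "\\2", params),
         sub("t$", "", params))
}

#' Classify parameters as regulatory (Et) or biochemical (kcat/KM)
#'
#' @inheritParams param_enzyme
#' @return logical vector, `TRUE` for enzyme-concentration parameters.
#' @export
is_regulatory <- function(params) grepl("t$", params) & !grepl("^(k|Km)_", params)

.new_pathway_model <- function(topology, reactions, params, boundary,
                               f35ph_substrates = c("DHK", "DHQ")) {
  structure(
    list(topology = topology,
         reactions = reactions,
         params = params,
         boundary = boundary,
         f35ph_substrates = f35ph_substrates,
         species = if (topology == "full") .SPECIES_FULL else .SPECIES_LINEAR,
         evolvable = names(params)),
    class = "pathway_model")
}

.apply_overrides <- function(params, boundary, overrides) {
  if (is.null(overrides) || length(overrides) == 0)
    return(list(params = params, boundary = boundary))
  overrides <- unlist(overrides)
  bad <- setdiff(names(overrides), c(names(params), names(boundary)))
  if (length(bad) > 0)
    stop("unknown parameter name(s) in overrides: ",
         paste(bad, collapse = ", "))
  for (nm in names(overrides)) {
    if (nm %in% names(params)) params[[nm]] <- overrides[[nm]]
    else boundary[[nm]] <- overrides[[nm]]
  }
  list(params = params, boundary = boundary)
}

#' Build the full branched anthocyanin pathway model
#'
#' Constructs the branched flavonoid network: CHS, CHI and F3H feed the
#' dihydroflavonol pool (DHK), which is partitioned by the hydroxylases
#' (F3'H: DHK->DHQ; F3'5'H: DHK->DHM and DHQ->DHM by default), by DFR
#' (towards the three leucoanthocyanidins and on via ANS to pelargonidin,
#' cyanidin and delphinidin) and by FLS (towards the flavonols kaempferol,
#' quercetin and myricetin). PCoA is held at a fixed concentration and the
#' six end products are drained by a shared first-order sink.
#'
#' In the naive state every kcat, every KM and every Et share one common
#' value (1 in the model's dimensionless units), as do the boundary
#' constants `PCoA` and `ksink`. The naive state is scale-free in the sense
#' that the pigment ratios the simulator selects on do not depend on the
#' common value chosen.
#'
#' @param naive_value_overrides optional named list/vector overriding
#'   registered parameters (kinetic parameters, Et values, or the boundary
#'   constants `PCoA` and `ksink`). Unknown names are an error.
#' @param f35ph_substrates substrates accepted by F3'5'H: the default
#'   `c("DHK", "DHQ")` follows the branched topology with flux into DHM from
#'   both dihydroflavonols; `"DHQ"` gives the strictly sequential
#'   hydroxylation variant.
#' @return a `pathway_model` object.
#' @export
build_full_pathway <- function(naive_value_overrides = NULL,
                               f35ph_substrates = c("DHK", "DHQ")) {
  f35ph_substrates <- match.arg(f35ph_substrates, c("DHK", "DHQ"),
                                several.ok = TRUE)
  rx <- .reactions_full(f35ph_substrates)
  nm <- .registry_names(rx)
  params <- stats::setNames(rep(1, length(nm)), nm)
  boundary <- c(PCoA = 1, ksink = 1)
  ov <- .apply_overrides(params, boundary, naive_value_overrides)
  .new_pathway_model("full", rx, ov$params, ov$boundary, f35ph_substrates)
}

#' Build the linear pelargonidin sub-pathway model
#'
#' The unbranched chain CHS -> CHI -> F3H -> DFR(DHK) -> ANS(LCP) -> pel with
#' the PCoA boundary and the pelargonidin sink, initialized with the naive
#' full-model parameter values.
#'
#' @inheritParams build_full_pathway
#' @return a `pathway_model` object with `topology == "linear"`.
#' @export
build_linear_pathway <- function(naive_value_overrides = NULL) {
  rx <- .reactions_linear()
  nm <- .registry_names(rx)
  params <- stats::setNames(rep(1, length(nm)), nm)
  boundary <- c(PCoA = 1, ksink = 1)
  ov <- .apply_overrides(params, boundary, naive_value_overrides)
  .new_pathway_model("linear", rx, ov$params, ov$boundary)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model: %s topology>\n", x$topology))
  cat(sprintf("  %d species, %d enzymatic reactions, %d sink processes\n",
              length(x$species), nrow(x$reactions),
              length(intersect(x$species, .END_PRODUCTS))))
  cat(sprintf("  %d evolvable parameters; PCoA = %g, ksink = %g\n",
              length(x$evolvable), x$boundary[["PCoA"]],
              x$boundary[["ksink"]]))
  invisible(x)
}

#' Generalized irreversible Michaelis-Menten rate with substrate competition
#'
#' Computes v = Et * kcat * \[S\] / (KM * (1 + sum_j \[S_j\]/KM_j)) where the
#' sum runs over all substrates of the enzyme, including S itself. With no
#' co-substrates this reduces to the familiar Et*kcat*\[S\]/(KM + \[S\]).
#'
#' @param reaction a list (or one-row data frame) with fields `kcat`, `km`,
#'   and `substrate`.
#' @param et enzyme concentration (>= 0).
#' @param substrate_concs named numeric vector of species concentrations;
#'   must contain the reaction substrate and all competitor substrates.
#' @param competitors optional data frame/list with fields `substrate` and
#'   `km` for the enzyme's co-substrates (excluding the focal substrate).
#' @return the reaction rate (never negative).
#' @export
reaction_rate <- function(reaction, et, substrate_concs, competitors = NULL) {
  s <- substrate_concs[[reaction$substrate]]
  if (any(substrate_concs < 0)) stop("negative substrate concentration")
  if (et < 0) stop("negative enzyme concentration")
  denom <- 1 + s / reaction$km
  if (!is.null(competitors) && length(competitors$substrate) > 0) {
    cs <- unlist(substrate_concs[competitors$substrate])
    denom <- denom + sum(cs / competitors$km)
  }
  et * reaction$kcat * s / (reaction$km * denom)
}

# reaction table with numeric kcat/km columns resolved from the registry
.reactions_with_kinetics <- function(model) {
  rx <- model$reactions
  rx$kcat <- unname(model$params[paste0("k_", rx$enzyme, "_", rx$substrate)])
  rx$km <- unname(model$params[paste0("Km_", rx$enzyme, "_", rx$substrate)])
  rx$et <- unname(model$params[paste0(rx$enzyme, "t")])
  rx
}

#' Evaluate all reaction rates of a model at given concentrations
#'
#' @param model a `pathway_model`.
#' @param concs named numeric vector of species concentrations.
#' @return named numeric vector of rates, one per enzymatic reaction
#'   (named `<ENZ>_<SUB>`), plus one `sink_<species>` rate per end product.
#' @export
model_rates <- function(model, concs) {
  rx <- .reactions_with_kinetics(model)
  v <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    comp <- rx[rx$enzyme == rx$enzyme[i] & seq_len(nrow(rx)) != i, ,
               drop = FALSE]
    v[i] <- reaction_rate(rx[i, ], rx$et[i], concs,
                          competitors = comp)
  }
  names(v) <- paste0(rx$enzyme, "_", rx$substrate)
  ends <- intersect(model$species, .END_PRODUCTS)
  sink <- model$boundary[["ksink"]] * unlist(concs[ends])
  names(sink) <- paste0("sink_", ends)
  c(v, sink)
}

# time-derivative of every dynamic species (PCoA held fixed); used by the
# deSolve fallback path
.model_derivs <- function(model, concs) {
  v <- model_rates(model, concs)
  rx <- model$reactions
  rxn <- paste0(rx$enzyme, "_", rx$substrate)
  d <- stats::setNames(numeric(length(model$species)), model$species)
  for (i in seq_len(nrow(rx))) {
    d[rx$substrate[i]] <- d[rx$substrate[i]] - v[rxn[i]]
    d[rx$product[i]] <- d[rx$product[i]] + v[rxn[i]]
  }
  ends <- intersect(model$species, .END_PRODUCTS)
  d[ends] <- d[ends] - model$boundary[["ksink"]] * unlist(concs[ends])
  d["PCoA"] <- 0
  d
}

#' Serialize a pathway model to JSON
#'
#' Writes species, reactions (with kcat/KM), enzyme concentrations and
#' boundary constants. The round trip `model_from_json(model_to_json(m))`
#' restores the model bit-exactly.
#'
#' @param model a `pathway_model`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  rx <- .reactions_with_kinetics(model)
  doc <- list(
    topology = model$topology,
    f35ph_substrates = model$f35ph_substrates,
    species = model$species,
    reactions = rx[, c("enzyme", "substrate", "product", "kcat", "km")],
    enzymes = as.list(model$params[paste0(unique(rx$enzyme), "t")]),
    boundary = as.list(model$boundary)
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a pathway model from JSON
#'
#' @param x a JSON string or a path to a JSON file written by
#'   [model_to_json()].
#' @return a `pathway_model`.
#' @export
model_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  rx <- doc$reactions
  overrides <- c(
    stats::setNames(rx$kcat, paste0("k_", rx$enzyme, "_", rx$substrate)),
    stats::setNames(rx$km, paste0("Km_", rx$enzyme, "_", rx$substrate)),
    unlist(doc$enzymes),
    unlist(doc$boundary)
  )
  if (doc$topology == "full")
    build_full_pathway(overrides, f35ph_substrates = doc$f35ph_substrates)
  else
    build_linear_pathway(overrides)
}

#' Replace parameter values in a model
#'
#' @param model a `pathway_model`.
#' @param params named numeric vector of registered parameter values.
#' @return the model with the values substituted.
#' @export
set_params <- function(model, params) {
  bad <- setdiff(names(params), c(names(model$params), names(model$boundary)))
  if (length(bad) > 0)
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  kin <- intersect(names(params), names(model$params))
  model$params[kin] <- params[kin]
  bnd <- intersect(names(params), names(model$boundary))
  model$boundary[bnd] <- params[bnd]
  model
}
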