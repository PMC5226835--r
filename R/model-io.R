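# Structured text (YAML) model definitions, so published models can be added
# without code changes.

#' Read or write a model definition file
#'
#' Models are stored as structured YAML with keys `name`, `species` (list of
#' `name`/`domain` entries), `stoichiometry` (list of integer rows, species by
#' flows), `flows` (list of `rate_coefficient`, `factors`, `regulators`),
#' `nl_parameters`, `cooperativity`, `moieties`, and optional
#' `reference_parameters` / `reference_state`. Factor entries use the same
#' fields as [FlowLaw-class]. SBML import is out of scope.
#'
#' @param path file path.
#' @param model a [ModelSpec-class] (for writing).
#' @return `readModelYAML()` a validated [ModelSpec-class];
#'   `writeModelYAML()` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeModelYAML(chainModel("negative"), f)
#' mod <- readModelYAML(f)
#' @export
readModelYAML <- function(path) {
  y <- yaml::read_yaml(path)
  species <- do.call(rbind, lapply(y$species, function(s)
    data.frame(name = s$name,
               domain = if (is.null(s$domain)) "concentration" else s$domain)))
  eta <- do.call(rbind, lapply(y$stoichiometry, as.integer))
  flows <- lapply(y$flows, function(f)
    flowLaw(f$rate_coefficient,
            factors = if (is.null(f$factors)) list() else f$factors,
            regulators = if (is.null(f$regulators)) character(0)
                         else unlist(f$regulators)))
  nl <- if (is.null(y$nl_parameters)) {
    data.frame(name = character(0), role = character(0))
  } else {
    do.call(rbind, lapply(y$nl_parameters, function(p)
      data.frame(name = p$name,
                 role = if (is.null(p$role)) "regulation" else p$role)))
  }
  coop <- if (is.null(y$cooperativity)) numeric(0) else unlist(y$cooperativity)
  moieties <- if (is.null(y$moieties)) list() else
    lapply(y$moieties, function(mo)
      list(species = unlist(mo$species), total = as.numeric(mo$total)))
  modelSpec(name = y$name, species = species, stoichiometry = eta,
            flows = flows, nlParameters = nl, cooperativity = coop,
            moieties = moieties,
            referenceParameters = if (is.null(y$reference_parameters))
              numeric(0) else unlist(y$reference_parameters),
            referenceState = if (is.null(y$reference_state))
              numeric(0) else unlist(y$reference_state))
}

#' @rdname readModelYAML
#' @export
writeModelYAML <- function(model, path) {
  y <- list(
    name = model@name,
    species = lapply(seq_len(nrow(model@species)), function(i)
      list(name = model@species$name[i], domain = model@species$domain[i])),
    stoichiometry = lapply(seq_len(nrow(model@stoichiometry)), function(i)
      as.integer(model@stoichiometry[i, ])),
    flows = lapply(model@flows, function(f) {
      out <- list(rate_coefficient = f@rateCoefficient, factors = f@factors)
      if (length(f@regulators)) out$regulators <- as.list(f@regulators)
      out
    }),
    nl_parameters = lapply(seq_len(nrow(model@nlParameters)), function(i)
      list(name = model@nlParameters$name[i],
           role = model@nlParameters$role[i])),
    cooperativity = as.list(model@cooperativity),
    moieties = lapply(model@moieties, function(mo)
      list(species = as.list(mo$species), total = mo$total)))
  if (length(model@referenceParameters))
    y$reference_parameters <- as.list(model@referenceParameters)
  if (length(model@referenceState))
    y$reference_state <- as.list(model@referenceState)
  yaml::write_yaml(y, path)
  invisible(path)
}
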