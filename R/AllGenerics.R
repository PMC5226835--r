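# Generics and accessors.

#' @describeIn ModelSpec-class number of species
#' @param object a `ModelSpec`
#' @export
setGeneric("nSpecies", function(object) standardGeneric("nSpecies"))

#' @describeIn ModelSpec-class number of flows
#' @export
setGeneric("nFlows", function(object) standardGeneric("nFlows"))

#' @describeIn ModelSpec-class species names
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @describeIn ModelSpec-class the stoichiometric matrix
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @describeIn ModelSpec-class list of flow laws
#' @export
setGeneric("flowLaws", function(object) standardGeneric("flowLaws"))

#' @describeIn ModelSpec-class nl-parameter table (name, role)
#' @export
setGeneric("nlParameters", function(object) standardGeneric("nlParameters"))

#' @describeIn ModelSpec-class fixed cooperativity parameters
#' @export
setGeneric("cooperativity", function(object) standardGeneric("cooperativity"))

#' @describeIn ModelSpec-class names of the rate coefficients (one per flow)
#' @export
setGeneric("rateCoefficientNames",
           function(object) standardGeneric("rateCoefficientNames"))

#' @describeIn ModelSpec-class names of all perturbable parameters (rate
#'   coefficients then nl-parameters; cooperativity parameters are excluded)
#' @export
setGeneric("perturbableParameters",
           function(object) standardGeneric("perturbableParameters"))

#' @describeIn ModelSpec-class published reference parameter set (if any)
#' @export
setGeneric("referenceParameters",
           function(object) standardGeneric("referenceParameters"))

#' @describeIn SampledParameterSet-class full named parameter vector
#'   (rate coefficients followed by nl-parameters)
#' @param object a `SampledParameterSet`
#' @export
setGeneric("parameterVector",
           function(object) standardGeneric("parameterVector"))

#' @describeIn SampledParameterSet-class sampled steady-state concentrations
#' @export
setGeneric("steadyState", function(object) standardGeneric("steadyState"))

#' @describeIn SampledParameterSet-class balanced steady-state flow vector
#' @export
setGeneric("steadyStateFlows",
           function(object) standardGeneric("steadyStateFlows"))

#' @describeIn RobustnessExperiment-class per-set sensitivity records
#' @param object a `RobustnessExperiment`
#' @export
setGeneric("sensitivityRecords",
           function(object) standardGeneric("sensitivityRecords"))

#' @describeIn RobustnessExperiment-class long-format per-parameter
#'   sensitivity coefficients
#' @export
setGeneric("sensitivityCoefficientTable",
           function(object) standardGeneric("sensitivityCoefficientTable"))

#' @describeIn RobustnessExperiment-class sampling and discard accounting
#' @export
setGeneric("runAccounting", function(object) standardGeneric("runAccounting"))
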