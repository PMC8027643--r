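#' Distribution profile of one descriptor
#'
#' Minimum, maximum, mean and the requested percentiles (linear
#' interpolation between closest ranks, i.e. `stats::quantile` type 7;
#' the method name is recorded in the result for reproducibility).
#'
#' @param values non-empty numeric vector.
#' @param qs percentiles in \[0, 100\] (default 90 and 95).
#' @return named list: `min`, `max`, `mean`, `percentiles` (named vector),
#'   `method`.
#' @examples
#' descriptorProfile(1:100, 90)$percentiles   # 90.1
#' @export
descriptorProfile <- function(values, qs = c(90, 95)) {
    if (length(values) == 0L) stop("empty vector")
    pct <- stats::quantile(values, qs / 100, type = 7, names = FALSE)
    list(min = min(values), max = max(values), mean = mean(values),
         percentiles = stats::setNames(pct, paste0("p", qs)),
         method = "linear interpolation (type 7)")
}

#' Permeability-rule evaluation for one peptide's descriptors
#'
#' Three rule sets over the structure-based descriptors:
#' \describe{
#'   \item{RO5}{Lipinski rule of five: MW <= 500, cLogP <= 5, HBD <= 5,
#'     HBA <= 10 (all inclusive).}
#'   \item{Veber}{NRB <= 10 and tPSA <= 140 (inclusive).}
#'   \item{extended}{the wider oral-bioavailability bounds: NRB < 20
#'     (strict) and -2 <= cLogP <= 10.}
#' }
#'
#' @param sd named vector containing at least MW, cLogP, tPSA, NRB, HBD,
#'   HBA (e.g. from [structDescriptors()]).
#' @return named list per rule: `pass` (logical) and `failing`
#'   (character vector of the violated sub-conditions).
#' @examples
#' permeabilityRuleFlags(structDescriptors("GG"))$RO5$pass   # TRUE
#' @export
permeabilityRuleFlags <- function(sd) {
    need <- c("MW", "cLogP", "tPSA", "NRB", "HBD", "HBA")
    if (!all(need %in% names(sd)))
        stop("descriptors must include ", paste(need, collapse = ", "))
    if (any(!is.finite(sd[need])))
        stop("descriptors must be finite")
    ruleOf <- function(conds) {
        failing <- names(conds)[!unlist(conds)]
        list(pass = length(failing) == 0L, failing = failing)
    }
    list(
        RO5 = ruleOf(list(
            "MW <= 500" = sd[["MW"]] <= 500,
            "cLogP <= 5" = sd[["cLogP"]] <= 5,
            "HBD <= 5" = sd[["HBD"]] <= 5,
            "HBA <= 10" = sd[["HBA"]] <= 10)),
        Veber = ruleOf(list(
            "NRB <= 10" = sd[["NRB"]] <= 10,
            "tPSA <= 140" = sd[["tPSA"]] <= 140)),
        extended = ruleOf(list(
            "NRB < 20" = sd[["NRB"]] < 20,
            "-2 <= cLogP <= 10" = sd[["cLogP"]] >= -2 &&
                sd[["cLogP"]] <= 10)))
}

#' Chemical-space report for a peptide library
#'
#' Per-descriptor distribution profiles plus per-rule violation counts
#' and fractions over the library.
#'
#' @param x a [PeptideSet-class] or a structural-descriptor matrix from
#'   [structDescriptorMatrix()].
#' @param qs percentiles to profile (default 90 and 95).
#' @return list with `profiles` (per descriptor), `rules` (per rule:
#'   `violations`, `fraction`), `n`, and `percentileMethod`.
#' @export
chemSpaceReport <- function(x, qs = c(90, 95)) {
    feat <- if (is(x, "PeptideSet")) structDescriptorMatrix(x) else
        as.matrix(x)
    profiles <- lapply(stats::setNames(nm = colnames(feat)), function(f)
        descriptorProfile(feat[, f], qs))
    flags <- apply(feat, 1L, permeabilityRuleFlags)
    rules <- lapply(stats::setNames(nm = c("RO5", "Veber", "extended")),
        function(r) {
            viol <- sum(!vapply(flags, function(fl) fl[[r]]$pass,
                                logical(1)))
            list(violations = viol, fraction = viol / nrow(feat))
        })
    list(profiles = profiles, rules = rules, n = nrow(feat),
         percentileMethod = "linear interpolation (type 7)")
}

#' Write a chemical-space report as JSON
#'
#' @param report result of [chemSpaceReport()].
#' @param path output file.
#' @export
writeChemSpaceReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
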