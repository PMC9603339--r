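#' Causal-factor taxonomy registry
#'
#' The coding scheme for hazardous-materials transportation accident causes:
#' six general-cause families -- Human (H), Vehicle (V), Hazardous Materials
#' (HM), Management (M), Environment (E) and Accident type (A) -- with 67
#' atomic specific causes in total. Accident-type codes are single-digit
#' (`A1`-`A9`); all other families are two-digit zero-padded (`H01`, `HM03`).
#'
#' @return A data frame with columns `code`, `category` and `label`, one row
#'   per atomic cause (12 H + 16 V + 9 HM + 8 M + 13 E + 9 A = 67 rows).
#' @examples
#' reg <- factor_registry()
#' nrow(reg)            # 67
#' subset(reg, code == "V12")$label
#' @export
factor_registry <- function() {
  .registry_df
}

.registry_entries <- list(
  H = c("Fatigue driving", "Improper avoidance", "Fast driving",
        "Improper braking", "Improper overtaking", "Improper operation",
        "Overload transportation", "Distracted driving", "Unsafe distance",
        "Unfamiliar with the road", "Other hazmat personnel reasons",
        "Non-hazmat personnel reasons"),
  V = c("Tank equipment failure", "Valve loose", "Valve damaged",
        "Tank damaged", "Tank/valve aging", "Pipe rupture",
        "Other tank reasons", "Blow-out", "Transmission shaft fracture",
        "Brake system fault", "Vehicle out of control", "Tire overheating",
        "Equipment aging", "Oil tank damaged", "Other vehicle reasons",
        "Packaging issues"),
  HM = c("Explosive materials", "Gas", "Flammable liquid", "Flammable solid",
         "Oxidizing materials", "Toxic and infectious materials",
         "Radioactive materials", "Corrosive and irritant materials",
         "Miscellaneous hazmat"),
  M = c("Illegally refitting vehicles", "No supercargo",
        "Failure to clean tank as required", "Illegal transportation",
        "No hazmat qualification certificate",
        "No hazmat transportation license", "Inadequate safety check",
        "Other management reasons"),
  E = c("Downhill road", "Slippery road", "Turning road", "Poor road",
        "Other road reasons", "Traffic jam", "Multi-car collision",
        "Other traffic reasons", "Rain or snow weather", "Foggy weather",
        "High temperature", "Poor visibility", "Other environment reasons"),
  A = c("Collision", "Scrape", "Roll-over", "Fall-over", "Fire", "Leakage",
        "Explosion", "Poisoning", "Others")
)

# A-family codes are single-digit by convention; the rest zero-padded to 2.
.format_code <- function(family, num) {
  if (family == "A") paste0("A", num) else sprintf("%s%02d", family, num)
}

.registry_df <- local({
  rows <- lapply(names(.registry_entries), function(fam) {
    labs <- .registry_entries[[fam]]
    data.frame(code = vapply(seq_along(labs), function(i) .format_code(fam, i), ""),
               category = fam, label = labs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
})

#' Write the factor registry to CSV
#'
#' @param path Output file path. Columns are `code`, `category`, `label`.
#' @return `path`, invisibly.
#' @export
export_registry <- function(path) {
  utils::write.csv(factor_registry(), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
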