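#' Species and treatment vocabulary
#'
#' The experimental food web contains four bacterivorous ciliate consumers
#' and one predatory ciliate. Species are referred to throughout by
#' single-letter codes: `C` (*Colpidium*), `D` (*Dexiostoma*),
#' `P` (*Paramecium*), `S` (*Spirostomum*) and `Pd` (the predator
#' *Spathidium*). `C` and `D` are the focal competitor pair.
#'
#' @return `hoi_species()` returns a data frame with one row per species:
#'   `code`, `display_name` and `role` (`"consumer"` or `"predator"`).
#' @examples
#' hoi_species()
#' @export
hoi_species <- function() {
  data.frame(
    code = c("C", "D", "P", "S", "Pd"),
    display_name = c("Colpidium", "Dexiostoma", "Paramecium",
                     "Spirostomum", "Spathidium"),
    role = c("consumer", "consumer", "consumer", "consumer", "predator"),
    stringsAsFactors = FALSE
  )
}

# canonical ordering used for design-matrix columns and reports
SPECIES_CODES <- c("C", "D", "P", "S", "Pd")
CONSUMER_CODES <- c("C", "D", "P", "S")
PREDATOR_CODE <- "Pd"

TREATMENT_SPECIES <- list(
  CD    = c("C", "D"),
  CDP   = c("C", "D", "P"),
  CDS   = c("C", "D", "S"),
  CDPd  = c("C", "D", "Pd"),
  CDPPd = c("C", "D", "P", "Pd"),
  CDSPd = c("C", "D", "S", "Pd")
)

#' Treatment codes of the experimental design
#'
#' Six community compositions: the focal pair alone (`CD`), with a third
#' competitor (`CDP`, `CDS`), and each of those with the predator added
#' (`CDPd`, `CDPPd`, `CDSPd`).
#'
#' @return Character vector of the six treatment codes.
#' @export
treatment_codes <- function() names(TREATMENT_SPECIES)

#' Describe a treatment
#'
#' @param code One of the six treatment codes (see [treatment_codes()]).
#' @return A list with `code`, `species` (all species codes in the
#'   community), `consumers` (species excluding the predator) and
#'   `predator_present`.
#' @examples
#' treatment_info("CDPPd")
#' @export
treatment_info <- function(code) {
  code <- match.arg(code, names(TREATMENT_SPECIES))
  sp <- TREATMENT_SPECIES[[code]]
  list(
    code = code,
    species = sp,
    consumers = setdiff(sp, PREDATOR_CODE),
    predator_present = PREDATOR_CODE %in% sp
  )
}

#' @rdname treatment_info
#' @export
treatment_species <- function(code) treatment_info(code)$species

# order species codes canonically (C, D, third competitor, predator)
canonical_species_order <- function(codes) {
  codes[order(match(codes, SPECIES_CODES))]
}

is_known_treatment <- function(code) code %in% names(TREATMENT_SPECIES)
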