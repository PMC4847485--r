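# Bundled default vocabularies. The ethnicity dictionary and the two cue
# lexicons are best-effort reconstructions of the kind of lists a curation
# team would assemble (country names, adjectivals and demonyms mapped to
# top-level ancestry groups; sample-description and stage-cue words); they
# are NOT a published resource and make no claim of completeness. They give
# the synthetic corpora and the rule-based committee members realistic
# material to work with.

#' Default ethnicity term dictionary
#'
#' Maps ~70 surface terms (country names, adjectivals, demonyms) to 14
#' top-level ethnicity groups. Reconstructed, not an official curation
#' guideline list.
#'
#' @return a [term_dictionary()].
#' @export
default_ethnicity_dictionary <- function() {
  groups <- list(
    "European" = c("European", "Europeans", "Caucasian", "German", "Germans",
                   "Germany", "French", "France", "Italian", "Italy",
                   "Swedish", "Sweden", "British", "Finnish", "Finland",
                   "Dutch"),
    "East Asian" = c("East Asian", "Chinese", "China", "Han", "Japanese",
                     "Japan", "Korean", "Korea"),
    "South Asian" = c("South Asian", "Indian", "India", "Pakistani",
                      "Pakistan"),
    "Southeast Asian" = c("Southeast Asian", "Indonesian", "Indonesia",
                          "Filipino", "Thai", "Malay"),
    "Sub-Saharan African" = c("African", "Africans", "Nigerian", "Nigeria",
                              "Yoruba", "Ethiopian"),
    "African American" = c("African American", "African Americans"),
    "Hispanic or Latin American" = c("Hispanic", "Latino", "Mexican",
                                     "Mexico", "Brazilian", "Puerto Rican"),
    "Middle East/North African" = c("Middle Eastern", "Arab", "Egyptian",
                                    "Iranian", "Moroccan"),
    "Native American" = c("Native American", "Pima", "Amerindian"),
    "Oceanian" = c("Oceanian", "Polynesian", "Samoan", "Maori"),
    "Central Asian" = c("Central Asian", "Kazakh", "Uzbek"),
    "Afro-Caribbean" = c("Afro-Caribbean", "Jamaican", "Barbadian"),
    "Ashkenazi Jewish" = c("Ashkenazi", "Ashkenazim"),
    "Aboriginal Australian" = c("Aboriginal Australian", "Aboriginal Australians")
  )
  entries <- unlist(lapply(names(groups), function(g)
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])))
  term_dictionary(entries, name = "ethnicity-default")
}

#' Default ethnicity alias table
#'
#' Rewrites spelling variants of group names found in curated tables to the
#' canonical top-level form (e.g. the two orderings of the Middle
#' East/North African group). User-editable; passed to
#' [read_curated_table()].
#'
#' @return named character vector (alias -> canonical).
#' @export
default_ethnicity_aliases <- function() {
  c("North African/Middle East" = "Middle East/North African",
    "Middle East / North African" = "Middle East/North African",
    "Hispanic/Latin American" = "Hispanic or Latin American",
    "Afro Caribbean" = "Afro-Caribbean")
}

#' Default sample-description lexicon (65 terms)
#'
#' Words commonly found in descriptions of a study sample, used by the
#' rule-based positive/negative committee member. Reconstructed list.
#'
#' @return a [rule_lexicon()] with `purpose = "sample_description"`.
#' @export
default_sample_lexicon <- function() {
  rule_lexicon(c(
    "stage", "cohort", "cohorts", "participants", "participant", "subjects",
    "subject", "individuals", "individual", "patients", "patient", "cases",
    "case", "controls", "control", "sample", "samples", "recruited",
    "recruitment", "enrolled", "enrollment", "genotyped", "genotyping",
    "volunteers", "volunteer", "donors", "donor", "men", "women", "adults",
    "children", "twins", "families", "family", "probands", "proband",
    "unrelated", "healthy", "affected", "unaffected", "ascertained",
    "ascertainment", "consortium", "registry", "biobank", "panel", "series",
    "collection", "examined", "aged", "ancestry", "descent", "origin",
    "background", "ethnicity", "ethnic", "population", "populations",
    "nested", "longitudinal", "prospective", "retrospective", "community",
    "hospital", "clinic"
  ), purpose = "sample_description")
}

#' Default stage-cue lexicons (8 terms in total)
#'
#' Words signalling the initial (discovery) versus replication stage of a
#' study. Reconstructed list.
#'
#' @return list with elements `initial` and `replication`, each a
#'   [rule_lexicon()].
#' @export
default_stage_lexicons <- function() {
  list(
    initial = rule_lexicon(c("discovery", "initial", "screening", "first stage"),
                           purpose = "initial_cue"),
    replication = rule_lexicon(c("replication", "follow-up", "validation",
                                 "second stage"),
                               purpose = "replication_cue")
  )
}

# canonical phenotype -> synonyms (may be empty)
.phenotype_vocab <- function() {
  list(
    "Type 2 diabetes" = c("T2D", "non insulin dependent diabetes"),
    "Type 1 diabetes" = c("T1D"),
    "Body mass index" = c("BMI"),
    "Obesity" = character(),
    "Coronary artery disease" = c("CAD"),
    "Hypertension" = c("high blood pressure"),
    "Rheumatoid arthritis" = character(),
    "Crohn's disease" = character(),
    "Ulcerative colitis" = character(),
    "Asthma" = character(),
    "Schizophrenia" = character(),
    "Bipolar disorder" = character(),
    "Major depressive disorder" = c("depression"),
    "Alzheimer's disease" = character(),
    "Parkinson's disease" = character(),
    "Multiple sclerosis" = character(),
    "Breast cancer" = character(),
    "Prostate cancer" = character(),
    "Lung cancer" = character(),
    "Colorectal cancer" = character(),
    "Melanoma" = character(),
    "Height" = c("adult height"),
    "Waist circumference" = character(),
    "Waist-hip ratio" = character(),
    "HDL cholesterol" = character(),
    "LDL cholesterol" = character(),
    "Triglycerides" = character(),
    "Total cholesterol" = character(),
    "Blood pressure" = character(),
    "Fasting glucose" = character(),
    "Fasting insulin" = character(),
    "Uric acid levels" = character(),
    "Bone mineral density" = character(),
    "Age-related macular degeneration" = c("AMD"),
    "Glaucoma" = character(),
    "Psoriasis" = character(),
    "Systemic lupus erythematosus" = c("lupus"),
    "Celiac disease" = character(),
    "Atrial fibrillation" = character(),
    "Stroke" = character(),
    "Chronic kidney disease" = character(),
    "Gout" = character(),
    "Eye color" = character(),
    "Hair color" = character(),
    "Male-pattern baldness" = c("androgenetic alopecia"),
    "Smoking behavior" = character(),
    "Alcohol consumption" = character(),
    "Educational attainment" = character(),
    "Sleep duration" = character(),
    "Longevity" = character()
  )
}

#' Default phenotype term dictionary
#'
#' ~50 canonical disease/trait names plus a few synonyms and
#' abbreviations, all mapping surface term -> canonical phenotype. Doubles
#' as the synonym dictionary for the phenotype committee's synonym rule
#' (terms sharing a canonical entity are synonyms).
#'
#' @return a [term_dictionary()].
#' @export
default_phenotype_dictionary <- function() {
  vocab <- .phenotype_vocab()
  entries <- unlist(lapply(names(vocab), function(ph)
    stats::setNames(rep(ph, 1L + length(vocab[[ph]])), c(ph, vocab[[ph]]))))
  term_dictionary(entries, name = "phenotype-default")
}
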