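# Shared fixtures built in code. The three-row gold-standard snippet mirrors
# the published annotation example: one normal finding and two key findings
# that share the token "thumbs" (one continuous, one discontinuous).

snippet_corpus <- function() {
  phen_corpus(
    observation_id = c("F8D319161DE176F2", "DC00B8A9EDA2C78", "DC00B8A9EDA2C78"),
    text = c(
      "FACE: No facial abnormalities noted within the limitations of examination.",
      "HANDS FEET: Both thumbs are long and broad",
      "HANDS FEET: Both thumbs are long and broad"
    ),
    label = c("NORMF", "KEYF", "KEYF"),
    hpo_id = c("HP:0000271", "HP:0011304", "HP:0032524"),
    spans = c("6-35", "17-27,37-42", "17-32")
  )
}

# the raw file rendering, with the N/A polarity dialect
snippet_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "ObservationID\tText\tHPO\tPolarity\tSpans",
    "F8D319161DE176F2\tFACE: No facial abnormalities noted within the limitations of examination.\tHP:0000271\tX\t6-35",
    "DC00B8A9EDA2C78\tHANDS FEET: Both thumbs are long and broad\tHP:0011304\tN/A\t17-27, 37-42",
    "DC00B8A9EDA2C78\tHANDS FEET: Both thumbs are long and broad\tHP:0032524\tN/A\t17-32"
  ), path)
  path
}

# A sectioned observation with one key finding and two normal findings whose
# serialized target exercises colons inside surfaces and shared leading
# fragments ("NECK:" and "no").
neck_corpus <- function() {
  phen_corpus(
    observation_id = "OBSNECK",
    text = "NECK: Excess nuchal skin noted with no webbing, cysts.",
    label = c("KEYF", "NORMF", "NORMF"),
    hpo_id = NA_character_,
    spans = c("6-24", "0-5,36-46", "0-5,36-38,48-53")
  )
}

norm_toy_dictionary <- function() {
  tibble::tibble(
    hpo_id = c("HP:0001252", "HP:0001290", "HP:0002745", "HP:0025474",
               "HP:0100790", "HP:0004299"),
    surface = c("Hypotonia", "Generalized hypotonia", "Oral leukoplakia",
                "Erythematous plaque", "Hernia", "Hernia of the abdominal wall"),
    is_preferred = TRUE
  )
}
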