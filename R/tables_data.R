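# Internal reference data: the printed summary tables of the source corpus,
# used by fixture_from_tables() and by the generator defaults.  Counts are
# kept exactly as printed; two typographic artifacts in the ambiguity table
# are corrected to their canonical spellings ("finally", "Circumstance").

# relation-type distribution: tokens and unique expression types
.tab_relation_types <- data.frame(
  rel_type = c("Explicit", "Implicit", "AltLex", "NoRel"),
  tokens   = c(2636L, 3001L, 193L, 29L),
  types    = c(179L, 57L, 165L, NA_integer_),
  stringsAsFactors = FALSE
)

# sense distribution by relation type; single-sense rows at type level
.tab_senses_single <- data.frame(
  sense    = c("Alternative", "Background", "Cause", "Circumstance",
               "Concession", "Condition", "Conjunction", "Continuation",
               "Contrast", "Exception", "Instantiation", "Purpose",
               "Reinforcement", "Restatement", "Similarity", "Temporal"),
  Explicit = c(31L, 0L, 339L, 8L, 257L, 22L, 421L, 24L, 205L, 7L, 21L,
               616L, 22L, 69L, 5L, 394L),
  Implicit = c(3L, 132L, 98L, 221L, 70L, 0L, 641L, 831L, 75L, 2L, 53L,
               0L, 60L, 445L, 0L, 370L),
  AltLex   = c(3L, 1L, 105L, 1L, 2L, 0L, 3L, 0L, 2L, 0L, 14L, 1L, 19L,
               19L, 0L, 16L),
  stringsAsFactors = FALSE
)

# multiple-sense rows: ordered (sense1, sense2) pairs
.tab_senses_multi <- data.frame(
  sense1   = c("Cause", "Cause", "Cause", "Cause", "Concession",
               "Concession", "Condition", "Condition", "Conjunction",
               "Continuation", "Contrast", "Contrast", "Purpose",
               "Reinforcement", "Temporal", "Temporal"),
  sense2   = c("Background", "Conjunction", "Reinforcement", "Temporal",
               "Background", "Circumstance", "Circumstance", "Temporal",
               "Temporal", "Reinforcement", "Background", "Concession",
               "Conjunction", "Conjunction", "Circumstance",
               "Continuation"),
  Explicit = c(8L, 5L, 0L, 6L, 2L, 1L, 2L, 5L, 70L, 1L, 0L, 1L, 1L, 0L,
               92L, 1L),
  AltLex   = c(0L, 0L, 1L, 3L, 0L, 0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L,
               0L, 0L),
  stringsAsFactors = FALSE
)

# contextual ambiguity of explicit connectives: type-level sense inventory
# (first senses) and token counts
.tab_ambiguity <- list(
  list("accordingly", c("Cause", "Conjunction"), 2L),
  list("although", c("Concession", "Contrast"), 76L),
  list("and", c("Cause", "Concession", "Conjunction", "Continuation",
                "Purpose", "Temporal"), 274L),
  list("as", c("Cause", "Purpose", "Temporal"), 23L),
  list("both upon", c("Circumstance", "Temporal"), 2L),
  list("but", c("Concession", "Contrast"), 42L),
  list("by", c("Cause", "Purpose", "Temporal"), 262L),
  list("finally", c("Conjunction", "Temporal"), 21L),
  list("however", c("Concession", "Contrast"), 117L),
  list("in part by", c("Cause", "Purpose"), 3L),
  list("in particular", c("Instantiation", "Restatement"), 4L),
  list("in response to", c("Cause", "Circumstance", "Temporal"), 12L),
  list("in turn", c("Cause", "Conjunction", "Temporal"), 6L),
  list("in", c("Circumstance", "Purpose"), 3L),
  list("indeed", c("Circumstance", "Reinforcement"), 15L),
  list("on the other hand", c("Concession", "Contrast"), 6L),
  list("once", c("Circumstance", "Temporal"), 7L),
  list("second", c("Conjunction", "Temporal"), 3L),
  list("since", c("Cause", "Temporal"), 52L),
  list("so", c("Cause", "Restatement"), 7L),
  list("then", c("Restatement", "Temporal"), 91L),
  list("therefore", c("Cause", "Restatement"), 75L),
  list("thus", c("Cause", "Restatement"), 77L),
  list("upon", c("Circumstance", "Temporal"), 15L),
  list("when", c("Circumstance", "Condition", "Temporal"), 65L),
  list("while", c("Concession", "Conjunction", "Contrast", "Temporal"), 64L),
  list("whilst", c("Concession", "Contrast"), 4L)
)

# sense x IMRAD segment cells with the *printed* row totals (two rows are
# internally inconsistent as printed: Conjunction cells sum to 749,
# Temporal to 374; carried as-is, never repaired)
.tab_imrad <- data.frame(
  sense = c("Alternative", "Background", "Cause", "Circumstance",
            "Concession", "Condition", "Conjunction", "Continuation",
            "Contrast", "Exception", "Instantiation", "Purpose",
            "Reinforcement", "Restatement", "Similarity", "Temporal"),
  Introduction = c(4L, 24L, 80L, 11L, 59L, 1L, 105L, 80L, 26L, 1L, 17L,
                   93L, 14L, 63L, 0L, 41L),
  Methods      = c(3L, 7L, 16L, 7L, 3L, 6L, 100L, 121L, 9L, 2L, 0L, 84L,
                   3L, 47L, 0L, 259L),
  Results      = c(7L, 36L, 134L, 112L, 73L, 0L, 271L, 112L, 118L, 2L,
                   9L, 144L, 14L, 124L, 2L, 0L),
  Abstract     = c(0L, 15L, 33L, 13L, 21L, 1L, 78L, 17L, 12L, 0L, 3L,
                   35L, 4L, 29L, 0L, 22L),
  Discussion   = c(15L, 39L, 208L, 13L, 116L, 11L, 195L, 85L, 81L, 1L,
                   42L, 104L, 50L, 65L, 3L, 52L),
  printed_total = c(29L, 121L, 471L, 156L, 272L, 19L, 754L, 415L, 246L,
                    6L, 71L, 460L, 85L, 328L, 5L, 515L),
  stringsAsFactors = FALSE
)

# filler lexicon for synthetic source text; nonsense-flavored tokens chosen
# so that no filler word collides with any connective string
.filler_words <- c(
  "cytovar", "blastomir", "regulon", "promexin", "kinovex", "transtor",
  "nucleovar", "plasmind", "receptil", "signolin", "factorix", "bindome",
  "exprevol", "genotir", "pathwin", "modulex", "activor", "repressil",
  "domanix", "ligandol", "enhastor", "motifex", "clonatir", "vectorin",
  "assayol", "bufferix", "culturon", "stimulex", "inducto", "lysatir"
)
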