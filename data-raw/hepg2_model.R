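# Builds inst/extdata/hepg2_ccm.model.json, the packaged transcription of the
# HepG2 central carbon metabolism network (49 reactions, 45 balanced species,
# 31 regulatory links). Reaction equations are written as human-readable
# strings and parsed; structural invariants are asserted before serializing.
#
# Conventions:
#  * "_in" intracellular, "_ex" extracellular, "_nb" non-balanced (boundary).
#  * Reference direction = steady-state flux direction of the fed state;
#    glucose transport (r47) and alanine transport (r48) are therefore uptake
#    steps (extracellular -> intracellular).
#  * PRPP_in is a boundary sink (produced only, by r27); COA is a boundary
#    cofactor; water/protons/phosphate etc. are boundary.

suppressMessages(library(jsonlite))

rxn <- function(id, name, eq, act = character(), inh = character()) {
  list(id = id, name = name, eq = eq, activators = act, inhibitors = inh)
}

reactions <- list(
  rxn("r1",  "glucokinase", "GLC_in + ATP_in -> G6P_in + ADP_in + H_nb",
      inh = "F6P_in"),
  rxn("r2",  "glucose-6-phosphate isomerase", "G6P_in -> F6P_in",
      inh = "6PG_in"),
  rxn("r3",  "phosphofructokinase", "F6P_in + ATP_in -> F16P_in + ADP_in + H_nb",
      act = "AMP_in", inh = "CIT_in"),
  rxn("r4",  "fructose-bisphosphate aldolase", "F16P_in -> DHAP_in + GAP_in",
      inh = c("ADP_in", "ATP_in", "E4P_in", "F6P_in", "G1P_in", "G6P_in", "RIBO5P_in")),
  rxn("r5",  "triose-phosphate isomerase", "DHAP_in -> GAP_in",
      inh = "ATP_in"),
  rxn("r6",  "glyceraldehyde-3-phosphate dehydrogenase",
      "GAP_in + P_nb + NAD_in -> 13PG_in + NADH_in + H_nb",
      inh = c("ADP_in", "ATP_in")),
  rxn("r7",  "phosphoglycerate kinase", "13PG_in + ADP_in + H_nb -> G3P_in + ATP_in",
      inh = "AMP_in"),
  rxn("r8",  "phosphoglycerate mutase", "G3P_in -> G2P_in"),
  rxn("r9",  "pyruvate kinase", "PEP_in + ADP_in + H_nb -> PYR_in + ATP_in",
      act = c("G6P_in", "F6P_in", "G1P_in", "F16P_in"), inh = "ALA_in"),
  rxn("r10", "glucose-6-phosphate dehydrogenase",
      "G6P_in + NADP_in -> GL6P_in + NADPH_in + H_nb",
      inh = "ATP_in"),
  rxn("r11", "6-phosphogluconolactonase", "GL6P_in + H2O_nb -> 6PG_in + H_nb"),
  rxn("r12", "phosphogluconate dehydrogenase",
      "6PG_in + NADP_in -> RIBU5P_in + CO2_nb + NADPH_in"),
  rxn("r13", "ribose-5-phosphate isomerase", "RIBU5P_in -> RIBO5P_in"),
  rxn("r14", "ribulose-phosphate 3-epimerase", "RIBU5P_in -> XYL5P_in"),
  rxn("r15", "transketolase", "RIBO5P_in + XYL5P_in -> GAP_in + S7P_in"),
  rxn("r16", "transketolase", "XYL5P_in + E4P_in -> GAP_in + F6P_in"),
  rxn("r17", "phosphopyruvate hydratase", "G2P_in -> PEP_in + H2O_nb + H_nb"),
  rxn("r18", "lactate dehydrogenase", "PYR_in + NADH_in + H_nb -> LAC_in + NAD_in"),
  rxn("r19", "adenosinetriphosphatase", "ATP_in + H2O_nb -> ADP_in + P_nb + H_nb"),
  rxn("r20", "alanine transaminase", "ALA_in + AKG_in -> PYR_in + GLU_in"),
  rxn("r21", "phosphoglucomutase", "G6P_in -> G1P_in",
      inh = "F16P_in"),
  rxn("r22", "nadph consumption", "NADPH_in + A_nb -> NADP_in + AH_nb"),
  rxn("r23", "glycogen synthesis", "UTP_nb + G1P_in -> UDP_nb + GLYG_nb + H_nb + PP_nb",
      inh = "AMP_in"),
  rxn("r24", "transaldolase", "S7P_in + GAP_in -> F6P_in + E4P_in"),
  rxn("r25", "adenylate kinase", "ATP_in + AMP_in -> 2 ADP_in"),
  rxn("r26", "glycerol synthesis", "DHAP_in -> GLYCEROL_nb"),
  rxn("r27", "nucleotide synthesis", "RIBO5P_in + ATP_in -> PRPP_in + AMP_in + H_nb"),
  rxn("r28", "serine synthesis",
      "G3P_in + NAD_in + GLU_in + H2O_nb -> SER_in + P_nb + NADH_in + 2 H_nb + AKG_in"),
  rxn("r29", "citrate synthase", "OAC_in + ACCOA_in + H2O_nb -> CIT_in + COA_nb + H_nb"),
  rxn("r30", "aconitate hydratase", "CIT_in -> CISAC_in + H2O_nb"),
  rxn("r31", "aconitate hydratase", "CISAC_in + H2O_nb -> ISOCIT_in"),
  rxn("r32", "isocitrate dehydrogenase", "ISOCIT_in + NAD_in -> AKG_in + CO2_nb + NADH_in",
      act = "ADP_in"),
  rxn("r33", "succinate-CoA ligase", "SUCCOA_in + P_nb + ADP_in -> SUC_in + COA_nb + ATP_in"),
  rxn("r34", "fumarate hydratase", "FUM_in + H2O_nb -> MAL_in"),
  rxn("r35", "malate dehydrogenase", "MAL_in + NAD_in -> OAC_in + NADH_in + H_nb"),
  rxn("r36", "pyruvate dehydrogenase complex",
      "PYR_in + NAD_in + COA_nb -> CO2_nb + NADH_in + ACCOA_in",
      act = "AMP_in"),
  rxn("r37", "alpha-ketoglutarate dehydrogenase complex",
      "AKG_in + NAD_in + COA_nb -> SUCCOA_in + CO2_nb + NADH_in",
      act = "ADP_in", inh = "ATP_in"),
  rxn("r38", "pyruvate synthesis", "PYR_nb -> PYR_in"),
  rxn("r39", "valine leucine isoleucine metabolism", "ISOVALMET_nb -> SUCCOA_in",
      act = c("NAD_in", "AKG_in"), inh = c("GLU_in", "NADH_in")),
  rxn("r40", "succinate dehydrogenase",
      "SUC_in + 0.6 NAD_in + 0.2 O2_nb -> FUM_in + 0.6 NADH_in + 0.6 H_nb + 0.4 H2O_nb"),
  rxn("r41", "oxidative phosphorylation",
      "NADH_in + 0.5 O2_nb + 3.5 H_nb + 2.5 ADP_in + 2.5 P_nb -> NAD_in + 3.5 H2O_nb + 2.5 ATP_in"),
  rxn("r42", "alpha-ketoglutarate synthesis", "AKG_nb -> AKG_in"),
  rxn("r43", "malic enzyme", "MAL_in + NADP_in -> PYR_in + CO2_nb + NADPH_in"),
  rxn("r44", "glutamate dehydrogenase",
      "GLU_in + H2O_nb + NAD_in -> AKG_in + NH4_nb + NADH_in + H_nb"),
  rxn("r45", "lactate transport", "LAC_in -> LAC_ex"),
  rxn("r46", "pyruvate transport", "PYR_in -> PYR_ex"),
  rxn("r47", "glucose transport", "GLC_ex -> GLC_in"),
  rxn("r48", "alanine transport", "ALA_ex -> ALA_in"),
  rxn("r49", "serine transport", "SER_in -> SER_ex")
)

parse_eq <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  stopifnot(length(sides) == 2)
  out <- list()
  for (s in 1:2) {
    sign <- if (s == 1) -1 else 1
    terms <- strsplit(trimws(sides[s]), "+", fixed = TRUE)[[1]]
    for (tm in terms) {
      tm <- trimws(tm)
      parts <- strsplit(tm, " ", fixed = TRUE)[[1]]
      if (length(parts) == 2) {
        coef <- as.numeric(parts[1]); sp <- parts[2]
      } else {
        coef <- 1; sp <- parts[1]
      }
      stopifnot(!is.na(coef), nzchar(sp))
      out[[sp]] <- (if (is.null(out[[sp]])) 0 else out[[sp]]) + sign * coef
    }
  }
  out
}

# species table ---------------------------------------------------------------
# order follows the abbreviation list of the model description; within each
# conserved set the designated dependent species (AMP, NADPH, NADH) is last.
sp <- function(id, name, compartment, balanced, measured = FALSE)
  list(id = id, name = name, compartment = compartment,
       balanced = balanced, measured = measured)

species <- list(
  sp("GLC_ex",  "glucose (extracellular)",  "extracellular", TRUE, TRUE),
  sp("LAC_ex",  "lactate (extracellular)",  "extracellular", TRUE, TRUE),
  sp("PYR_ex",  "pyruvate (extracellular)", "extracellular", TRUE, TRUE),
  sp("ALA_ex",  "alanine (extracellular)",  "extracellular", TRUE, TRUE),
  sp("SER_ex",  "serine (extracellular)",   "extracellular", TRUE, TRUE),
  sp("GLC_in",  "glucose",                 "intracellular", TRUE, TRUE),
  sp("G6P_in",  "glucose-6-phosphate",     "intracellular", TRUE, TRUE),
  sp("G1P_in",  "glucose-1-phosphate",     "intracellular", TRUE),
  sp("F6P_in",  "fructose-6-phosphate",    "intracellular", TRUE),
  sp("F16P_in", "fructose-1,6-bisphosphate", "intracellular", TRUE, TRUE),
  sp("DHAP_in", "dihydroxyacetone phosphate", "intracellular", TRUE, TRUE),
  sp("GAP_in",  "glyceraldehyde 3-phosphate", "intracellular", TRUE),
  sp("13PG_in", "1,3-bisphospho-glycerate", "intracellular", TRUE),
  sp("G3P_in",  "3-phosphoglycerate",      "intracellular", TRUE, TRUE),
  sp("G2P_in",  "2-phosphoglycerate",      "intracellular", TRUE),
  sp("PEP_in",  "phosphoenolpyruvate",     "intracellular", TRUE, TRUE),
  sp("PYR_in",  "pyruvate",                "intracellular", TRUE, TRUE),
  sp("LAC_in",  "lactate",                 "intracellular", TRUE, TRUE),
  sp("ALA_in",  "alanine",                 "intracellular", TRUE, TRUE),
  sp("SER_in",  "serine",                  "intracellular", TRUE, TRUE),
  sp("GL6P_in", "6-phospho-glucono-1,5-lactone", "intracellular", TRUE),
  sp("6PG_in",  "6-phospho-gluconate",     "intracellular", TRUE, TRUE),
  sp("RIBU5P_in", "ribulose 5-phosphate",  "intracellular", TRUE, TRUE),
  sp("RIBO5P_in", "ribose 5-phosphate",    "intracellular", TRUE, TRUE),
  sp("XYL5P_in", "xylulose 5-phosphate",   "intracellular", TRUE),
  sp("S7P_in",  "sedoheptulose 7-phosphate", "intracellular", TRUE, TRUE),
  sp("E4P_in",  "erythrose 4-phosphate",   "intracellular", TRUE),
  sp("ACCOA_in", "acetyl-CoA",             "intracellular", TRUE),
  sp("CIT_in",  "citrate",                 "intracellular", TRUE, TRUE),
  sp("CISAC_in", "cis-aconitate",          "intracellular", TRUE, TRUE),
  sp("ISOCIT_in", "isocitrate",            "intracellular", TRUE, TRUE),
  sp("AKG_in",  "alpha-ketoglutarate",     "intracellular", TRUE),
  sp("SUCCOA_in", "succinyl-CoA",          "intracellular", TRUE),
  sp("SUC_in",  "succinate",               "intracellular", TRUE),
  sp("FUM_in",  "fumarate",                "intracellular", TRUE, TRUE),
  sp("MAL_in",  "malate",                  "intracellular", TRUE, TRUE),
  sp("OAC_in",  "oxaloacetate",            "intracellular", TRUE),
  sp("GLU_in",  "glutamate",               "intracellular", TRUE),
  sp("ATP_in",  "ATP",                     "intracellular", TRUE, TRUE),
  sp("ADP_in",  "ADP",                     "intracellular", TRUE, TRUE),
  sp("AMP_in",  "AMP",                     "intracellular", TRUE, TRUE),
  sp("NADP_in", "NADP",                    "intracellular", TRUE, TRUE),
  sp("NADPH_in", "NADPH",                  "intracellular", TRUE),
  sp("NAD_in",  "NAD",                     "intracellular", TRUE, TRUE),
  sp("NADH_in", "NADH",                    "intracellular", TRUE, TRUE),
  # boundary pools (held constant; no mass balance)
  sp("H_nb",    "proton",          "boundary", FALSE),
  sp("H2O_nb",  "water",           "boundary", FALSE),
  sp("P_nb",    "orthophosphate",  "boundary", FALSE),
  sp("PP_nb",   "pyrophosphate",   "boundary", FALSE),
  sp("CO2_nb",  "carbon dioxide",  "boundary", FALSE),
  sp("O2_nb",   "oxygen",          "boundary", FALSE),
  sp("NH4_nb",  "ammonium",        "boundary", FALSE),
  sp("UTP_nb",  "UTP",             "boundary", FALSE),
  sp("UDP_nb",  "UDP",             "boundary", FALSE),
  sp("GLYG_nb", "glycogen",        "boundary", FALSE),
  sp("GLYCEROL_nb", "glycerol",    "boundary", FALSE),
  sp("COA_nb",  "coenzyme A",      "boundary", FALSE),
  sp("A_nb",    "NADPH acceptor (lumped biosynthetic demand)", "boundary", FALSE),
  sp("AH_nb",   "reduced NADPH acceptor", "boundary", FALSE),
  sp("PYR_nb",  "pyruvate precursor pool", "boundary", FALSE),
  sp("AKG_nb",  "alpha-ketoglutarate precursor pool", "boundary", FALSE),
  sp("ISOVALMET_nb", "valine/leucine/isoleucine/methionine pool", "boundary", FALSE),
  sp("PRPP_in", "5-phospho-ribose 1-diphosphate (biosynthetic sink)", "boundary", FALSE)
)

ids <- vapply(species, `[[`, "", "id")
stopifnot(!anyDuplicated(ids))
balanced <- ids[vapply(species, `[[`, TRUE, "balanced")]
stopifnot(length(balanced) == 45)
stopifnot(sum(vapply(species, \(s) s$balanced && s$compartment == "extracellular", TRUE)) == 5)
stopifnot(sum(vapply(species, `[[`, TRUE, "measured")) == 30)

reactions <- lapply(reactions, function(r) {
  st <- parse_eq(r$eq)
  stopifnot(all(names(st) %in% ids),
            all(c(r$activators, r$inhibitors) %in% ids))
  list(id = r$id, name = r$name, stoichiometry = st,
       activators = I(r$activators), inhibitors = I(r$inhibitors))
})
stopifnot(length(reactions) == 49)
stopifnot(sum(lengths(lapply(reactions, `[[`, "inhibitors"))) == 21)
stopifnot(sum(lengths(lapply(reactions, `[[`, "activators"))) == 10)

# stoichiometric sanity: balanced rows must all be producible and consumable
N <- matrix(0, length(balanced), length(reactions),
            dimnames = list(balanced, vapply(reactions, `[[`, "", "id")))
for (r in reactions) {
  keep <- intersect(names(r$stoichiometry), balanced)
  N[keep, r$id] <- unlist(r$stoichiometry[keep])
}
intra <- ids[vapply(species, \(s) s$balanced && s$compartment == "intracellular", TRUE)]
stopifnot(all(rowSums(N[intra, ] > 0) > 0), all(rowSums(N[intra, ] < 0) > 0))
stopifnot(qr(N)$rank == 42)
# conserved sums
for (mo in list(c("ATP_in", "ADP_in", "AMP_in"), c("NAD_in", "NADH_in"),
                c("NADP_in", "NADPH_in")))
  stopifnot(max(abs(colSums(N[mo, , drop = FALSE]))) == 0)
# elasticity census: balanced reactants + modifiers
n_el <- sum(vapply(reactions, function(r)
  sum(names(r$stoichiometry) %in% balanced) +
    length(r$activators) + length(r$inhibitors), 0))
stopifnot(n_el == 174)

model <- list(
  name = "HepG2 central carbon metabolism, dynamic linlog model",
  notes = paste(
    "Reference directions follow the fed-state steady-state flux map;",
    "glucose (r47) and alanine (r48) transport are written as uptake steps.",
    "Intracellular concentrations in mmol/l cell volume, extracellular in",
    "mmol/l well volume; the reference flux vector J0 is expressed in the",
    "concentration unit of each species row it feeds."),
  species = species,
  reactions = reactions
)

json <- toJSON(model, auto_unbox = TRUE, digits = NA, pretty = TRUE)
writeLines(json, "inst/extdata/hepg2_ccm.model.json")
cat("wrote model:", length(species), "species,", length(reactions), "reactions\n")
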