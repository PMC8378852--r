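# Curated substrate library: labelled electrophiles and nucleophiles for
# every substrate class, used by the synthetic generator and as the
# classification fixture.

#' Curated, labelled substrate library
#'
#' At least three electrophiles per (leaving group x ring kind) class and
#' at least three nucleophiles per nitrogen class, with verified labels.
#' Includes the symmetric stress cases (piperazine, 1,4-dibromobenzene as
#' an extra), a benzo-fused heteroaryl bromide carrying the halide on its
#' carbocyclic ring, and the tautomeric stress case (an aminophenyl
#' hydroxypyridine whose product records draw the pyridone form;
#' `tautomer_case` flag).
#'
#' @return tibble with `name`, `smiles`, `role`
#'   (electrophile/nucleophile), `class`, `tautomer_case`.
#' @export
substrate_library <- function() {
  e <- function(name, smiles, class) {
    tibble::tibble(name = name, smiles = smiles, role = "electrophile",
                   class = class, tautomer_case = FALSE)
  }
  nu <- function(name, smiles, class, taut = FALSE) {
    tibble::tibble(name = name, smiles = smiles, role = "nucleophile",
                   class = class, tautomer_case = taut)
  }
  ots <- function(ar) paste0("Cc1ccc(cc1)S(=O)(=O)O", ar)
  otf <- function(ar) paste0("O=S(=O)(O", ar, ")C(F)(F)F")
  dplyr::bind_rows(
    # --- electrophiles: halides on carbocyclic aromatics (ARY)
    e("bromobenzene", "Brc1ccccc1", "Br_ARY"),
    e("4-bromotoluene", "Cc1ccc(Br)cc1", "Br_ARY"),
    e("4-bromoanisole", "COc1ccc(Br)cc1", "Br_ARY"),
    e("2-bromonaphthalene", "Brc1ccc2ccccc2c1", "Br_ARY"),
    e("chlorobenzene", "Clc1ccccc1", "Cl_ARY"),
    e("4-chlorotoluene", "Cc1ccc(Cl)cc1", "Cl_ARY"),
    e("4-chloroanisole", "COc1ccc(Cl)cc1", "Cl_ARY"),
    e("iodobenzene", "Ic1ccccc1", "I_ARY"),
    e("4-iodotoluene", "Cc1ccc(I)cc1", "I_ARY"),
    e("4-iodoanisole", "COc1ccc(I)cc1", "I_ARY"),
    e("fluorobenzene", "Fc1ccccc1", "F_ARY"),
    e("4-fluorotoluene", "Cc1ccc(F)cc1", "F_ARY"),
    e("4-fluoroanisole", "COc1ccc(F)cc1", "F_ARY"),
    # --- electrophiles: halides on heteroaromatics (HAR)
    e("2-bromopyridine", "Brc1ccccn1", "Br_HAR"),
    e("3-bromopyridine", "Brc1cccnc1", "Br_HAR"),
    e("2-bromopyrimidine", "Brc1ncccn1", "Br_HAR"),
    e("5-bromoquinoline", "Brc1cccc2ncccc12", "Br_HAR"),
    e("2-chloropyridine", "Clc1ccccn1", "Cl_HAR"),
    e("3-chloropyridine", "Clc1cccnc1", "Cl_HAR"),
    e("2-chloropyrimidine", "Clc1ncccn1", "Cl_HAR"),
    e("2-iodopyridine", "Ic1ccccn1", "I_HAR"),
    e("3-iodopyridine", "Ic1cccnc1", "I_HAR"),
    e("2-iodopyrimidine", "Ic1ncccn1", "I_HAR"),
    e("2-fluoropyridine", "Fc1ccccn1", "F_HAR"),
    e("3-fluoropyridine", "Fc1cccnc1", "F_HAR"),
    e("2-fluoropyrimidine", "Fc1ncccn1", "F_HAR"),
    # --- electrophiles: sulfonate esters
    e("phenyl triflate", otf("c1ccccc1"), "OTf_ARY"),
    e("4-methylphenyl triflate", otf("c1ccc(C)cc1"), "OTf_ARY"),
    e("naphthalen-2-yl triflate", otf("c1ccc2ccccc2c1"), "OTf_ARY"),
    e("pyridin-3-yl triflate", otf("c1cccnc1"), "OTf_HAR"),
    e("pyrimidin-5-yl triflate", otf("c1cncnc1"), "OTf_HAR"),
    e("quinolin-3-yl triflate", otf("c1cnc2ccccc2c1"), "OTf_HAR"),
    e("phenyl tosylate", ots("c1ccccc1"), "OTs_ARY"),
    e("4-methoxyphenyl tosylate", ots("c1ccc(OC)cc1"), "OTs_ARY"),
    e("naphthalen-2-yl tosylate", ots("c1ccc2ccccc2c1"), "OTs_ARY"),
    e("pyridin-3-yl tosylate", ots("c1cccnc1"), "OTs_HAR"),
    e("pyrimidin-5-yl tosylate", ots("c1cncnc1"), "OTs_HAR"),
    e("quinolin-3-yl tosylate", ots("c1cnc2ccccc2c1"), "OTs_HAR"),
    # --- nucleophiles
    nu("aniline", "Nc1ccccc1", "Aryl"),
    nu("p-toluidine", "Cc1ccc(N)cc1", "Aryl"),
    nu("p-anisidine", "COc1ccc(N)cc1", "Aryl"),
    nu("3,5-dimethylaniline", "Cc1cc(C)cc(N)c1", "Aryl"),
    nu("diphenylamine", "c1ccc(Nc2ccccc2)cc1", "DiAryl"),
    nu("di-p-tolylamine", "Cc1ccc(Nc2ccc(C)cc2)cc1", "DiAryl"),
    nu("N-phenylnaphthalen-2-amine", "c1ccc(Nc2ccc3ccccc3c2)cc1", "DiAryl"),
    nu("benzylamine", "NCc1ccccc1", "Alkyl"),
    nu("n-butylamine", "CCCCN", "Alkyl"),
    nu("cyclohexylamine", "NC1CCCCC1", "Alkyl"),
    nu("morpholine", "C1COCCN1", "DiAlkyl"),
    nu("piperidine", "C1CCNCC1", "DiAlkyl"),
    nu("pyrrolidine", "C1CCNC1", "DiAlkyl"),
    nu("piperazine", "C1CNCCN1", "DiAlkyl"),
    nu("N-methylaniline", "CNc1ccccc1", "AlkylAryl"),
    nu("N-ethylaniline", "CCNc1ccccc1", "AlkylAryl"),
    nu("indoline", "C1Cc2ccccc2N1", "AlkylAryl"),
    nu("carbazole", "c1ccc2c(c1)[nH]c1ccccc12", "aromN"),
    nu("indole", "c1ccc2[nH]ccc2c1", "aromN"),
    nu("pyrrole", "c1cc[nH]c1", "aromN"),
    nu("pyrazole", "c1cc[nH]n1", "aromN"),
    nu("benzophenone imine", "N=C(c1ccccc1)c1ccccc1", "Ketimine"),
    nu("acetophenone imine", "CC(=N)c1ccccc1", "Ketimine"),
    nu("cyclohexanone imine", "N=C1CCCCC1", "Ketimine"),
    nu("benzamide", "NC(=O)c1ccccc1", "Amide"),
    nu("acetamide", "CC(N)=O", "Amide"),
    nu("2-pyrrolidinone", "O=C1CCCN1", "Amide"),
    nu("acetanilide", "CC(=O)Nc1ccccc1", "Amide"),
    nu("ammonia", "N", "Other"),
    nu("O-methylhydroxylamine", "CON", "Other"),
    nu("hydrazine", "NN", "Other"),
    nu("4-(6-hydroxypyridin-3-yl)aniline", "Nc1ccc(-c2ccc(O)nc2)cc1",
       "Aryl", taut = TRUE)
  )
}

#' The 25-substrate classification fixture
#'
#' A labelled subset of [substrate_library()]: one electrophile per
#' (leaving group x ring kind) class, one nucleophile per nitrogen class,
#' plus the symmetric piperazine, the amide-over-AlkylAryl acetanilide,
#' the carbocyclic-ring quinolinyl bromide, and the tautomeric
#' hydroxypyridine/pyridone case.
#'
#' @return 25-row tibble, same columns as [substrate_library()].
#' @export
classification_fixture <- function() {
  lib <- substrate_library()
  pick <- c("bromobenzene", "chlorobenzene", "iodobenzene", "fluorobenzene",
            "2-bromopyridine", "2-chloropyridine", "2-iodopyridine",
            "2-fluoropyridine", "phenyl triflate", "pyridin-3-yl triflate",
            "phenyl tosylate", "pyridin-3-yl tosylate", "5-bromoquinoline",
            "aniline", "diphenylamine", "benzylamine", "morpholine",
            "N-methylaniline", "carbazole", "benzophenone imine",
            "benzamide", "ammonia", "piperazine", "acetanilide",
            "4-(6-hydroxypyridin-3-yl)aniline")
  out <- lib[match(pick, lib$name), ]
  stopifnot(nrow(out) == 25, !anyNA(out$smiles))
  out
}
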