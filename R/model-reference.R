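#' Build the reference CD4+ T cell differentiation model
#'
#' Constructs the full reaction network coupling the cytokine milieu to the
#' four master regulators (T-bet, GATA3, RORgt, FOXP3) and the nuclear
#' receptor PPARg: 93 species, 52 reactions, 60 ODEs. The network is organised
#' in four motif families:
#'
#' * eight two-chain receptor modules (`ligand + chain1 + chain2 -> complex`,
#'   mass action, with the receptor-associated kinase as a constant catalyst
#'   and dissociation back to free chains);
#' * six STAT/SMAD phosphorylation cycles driven by the receptor complexes
#'   (Hill activation, phosphatase-catalysed mass-action dephosphorylation);
#' * five transcription-factor activation cycles with mutual inhibition
#'   (GATA3 -| T-bet, T-bet -| GATA3, FOXP3/PPARg/SMRT -| RORgt,
#'   STAT3-P -| FOXP3) and PPARg catalysing FOXP3 induction;
#' * seven signature-cytokine production cycles read out downstream of the
#'   master regulators.
#'
#' The 33 boundary species are the external cytokines (including IL-23, whose
#' receptor module is a terminal input branch), the two neutralizing
#' antibodies, a PPARg ligand pool (endogenous agonist tone; drug dosing and
#' dose scans clamp activated PPARg directly, see [agonist_clamp()]), twelve
#' constant gene loci and constant kinase/phosphatase/cofactor pools.
#'
#' Kinetic constants are package-calibrated to reproduce the qualitative
#' stimulus-to-fate behavior of the biological system (the model metadata is
#' tagged `calibration = "recalibrated"`); all levels are in arbitrary units
#' with conserved unit-sized pools per cycle, and time is in hours.
#'
#' @return A `cd4_model` with metadata `expected_counts = c(93, 52, 60)`.
#' @examples
#' m <- build_reference_model()
#' n_species(m); n_reactions(m); n_odes(m)
#' @export
build_reference_model <- function() {
  sp <- list()
  rx <- list()
  par <- c()
  add_sp <- function(...) sp[[length(sp) + 1L]] <<- cd4_species(...)
  add_rx <- function(r) rx[[length(rx) + 1L]] <<- r
  add_par <- function(v) par <<- c(par, v)

  ## ---- boundary inputs -------------------------------------------------
  ext <- c(IFNg_e = "external IFN-gamma", IL12_e = "external IL-12",
           IL18_e = "external IL-18", IL4_e = "external IL-4",
           IL6_e = "external IL-6", TGFb_e = "external TGF-beta",
           IL2_e = "external IL-2", IL23_e = "external IL-23")
  for (id in names(ext)) {
    add_sp(id, ext[[id]], "external_cytokine", 0, TRUE)
  }
  add_sp("aIL4", "neutralizing anti-IL-4 antibody", "neutralizing_antibody", 0, TRUE)
  add_sp("aIFNg", "neutralizing anti-IFN-gamma antibody", "neutralizing_antibody", 0, TRUE)
  add_sp("PPARg_lig", "PPARg ligand pool (endogenous tone)", "signal_transducer", 0.3, TRUE)
  genes <- c(Tbet_g = "Tbx21 locus", GATA3_g = "Gata3 locus",
             RORgt_g = "Rorc locus", FOXP3_g = "Foxp3 locus",
             PPARg_g = "Pparg locus", IFNg_g = "Ifng locus",
             IL4_g = "Il4 locus", IL17_g = "Il17a locus",
             IL21_g = "Il21 locus", TGFb_g = "Tgfb1 locus",
             IL10_g = "Il10 locus", IL2_g = "Il2 locus")
  for (id in names(genes)) add_sp(id, genes[[id]], "signal_transducer", 1, TRUE)
  cof <- c(JAK1 = "Janus kinase 1", JAK2 = "Janus kinase 2",
           JAK3 = "Janus kinase 3", TYK2 = "tyrosine kinase 2",
           MYD88 = "MyD88 adaptor", SHP1 = "SHP phosphatase pool",
           Prot = "proteasomal turnover pool", SMRT = "SMRT corepressor",
           RXR = "retinoid X receptor", SMAD4 = "SMAD4 cofactor")
  for (id in names(cof)) add_sp(id, cof[[id]], "signal_transducer", 1, TRUE)

  ## ---- receptor modules ------------------------------------------------
  receptor <- function(tag, ligand, c1, c2, kinase = NULL, antibody = NULL,
                       k_bind = 1, k_unbind = 1) {
    cx <- paste0(tag, "_c")
    add_sp(c1, paste(tag, "chain", c1), "receptor", 1, FALSE)
    add_sp(c2, paste(tag, "chain", c2), "receptor", 1, FALSE)
    add_sp(cx, paste("signaling", tag, "complex"), "receptor", 0, FALSE)
    subs <- stats::setNames(rep(1, 3 + !is.null(kinase)),
                            c(ligand, c1, c2, kinase))
    bid <- paste0("bind_", tag)
    add_par(stats::setNames(k_bind, paste0(bid, ".k")))
    add_rx(cd4_reaction(bid, substrates = subs,
                        products = stats::setNames(1, cx),
                        rate_law = ma_law(paste0(bid, ".k")),
                        modifiers = antibody %||% character()))
    uid <- paste0("unbind_", tag)
    add_par(stats::setNames(k_unbind, paste0(uid, ".k")))
    add_rx(cd4_reaction(uid, substrates = stats::setNames(1, cx),
                        products = stats::setNames(c(1, 1), c(c1, c2)),
                        rate_law = ma_law(paste0(uid, ".k"))))
    cx
  }

  IFNgR_c <- receptor("IFNgR", "IFNg_e", "IFNGR1", "IFNGR2", "JAK1", "aIFNg")
  IL12R_c <- receptor("IL12R", "IL12_e", "IL12RB1", "IL12RB2", "TYK2")
  IL18R_c <- receptor("IL18R", "IL18_e", "IL18R1", "IL18RAP", "MYD88")
  IL4R_c  <- receptor("IL4R", "IL4_e", "IL4RA", "IL4RG", "JAK3", "aIL4")
  IL6R_c  <- receptor("IL6R", "IL6_e", "IL6RA", "GP130", "JAK2")
  TGFbR_c <- receptor("TGFbR", "TGFb_e", "TGFBR1", "TGFBR2")
  IL2R_c  <- receptor("IL2R", "IL2_e", "IL2RA", "IL2RB", "JAK3")
  IL23R_c <- receptor("IL23R", "IL23_e", "IL23R1", "IL12RB1b", "TYK2")

  ## ---- conserved activation cycles ------------------------------------
  # pre -> act: hill(driver) * pre * catalysts * inhibition; act -> pre: ma.
  cycle <- function(pre, act, role, driver, vmax, km, n,
                    inhibitors = c(), catalysts = character(),
                    k_back, back_cat = NULL,
                    init_pre = 1, init_act = 0,
                    pre_name = pre, act_name = act) {
    add_sp(pre, pre_name, role, init_pre, FALSE)
    add_sp(act, act_name, role, init_act, FALSE)
    aid <- paste0("act_", act)
    pn <- stats::setNames(c(vmax, km, n),
                          paste0(aid, c(".vmax", ".km", ".n")))
    ki_names <- character()
    if (length(inhibitors)) {
      ki_names <- paste0(aid, ".ki_", names(inhibitors))
      pn <- c(pn, stats::setNames(unname(inhibitors), ki_names))
    }
    add_par(pn)
    add_rx(cd4_reaction(aid, substrates = stats::setNames(1, pre),
                        products = stats::setNames(1, act),
                        rate_law = hill_law(
                          vmax = paste0(aid, ".vmax"),
                          km = paste0(aid, ".km"),
                          n = paste0(aid, ".n"),
                          driver = driver,
                          inhibitors = stats::setNames(ki_names, names(inhibitors)),
                          catalysts = c(pre, catalysts))))
    iid <- paste0("inact_", act)
    add_par(stats::setNames(k_back, paste0(iid, ".k")))
    subs <- stats::setNames(rep(1, 1 + !is.null(back_cat)), c(act, back_cat))
    add_rx(cd4_reaction(iid, substrates = subs,
                        products = stats::setNames(1, pre),
                        rate_law = ma_law(paste0(iid, ".k"))))
    invisible(act)
  }

  # STAT/SMAD phosphorylation cycles (driver = receptor complex)
  cycle("STAT1", "STAT1_P", "signal_transducer", IFNgR_c,
        vmax = 2, km = 0.15, n = 1, k_back = 1, back_cat = "SHP1")
  cycle("STAT4", "STAT4_P", "signal_transducer", IL12R_c,
        vmax = 2, km = 0.15, n = 1, catalysts = IL18R_c,
        k_back = 1, back_cat = "SHP1")
  cycle("STAT6", "STAT6_P", "signal_transducer", IL4R_c,
        vmax = 2, km = 0.15, n = 1, k_back = 1, back_cat = "SHP1")
  cycle("STAT3", "STAT3_P", "signal_transducer", IL6R_c,
        vmax = 2, km = 0.15, n = 1, inhibitors = c(PPARg_a = 0.4),
        k_back = 1, back_cat = "SHP1")
  cycle("STAT5", "STAT5_P", "signal_transducer", IL2R_c,
        vmax = 2, km = 0.15, n = 1, k_back = 1, back_cat = "SHP1")
  cycle("SMAD3", "SMAD3_P", "signal_transducer", TGFbR_c,
        vmax = 2, km = 0.15, n = 1, catalysts = "SMAD4",
        k_back = 1, back_cat = "SHP1")

  # Master-regulator activation cycles
  cycle("Tbet_pre", "Tbet", "transcription_factor", "STAT1_P",
        vmax = 0.4, km = 0.3, n = 2, inhibitors = c(GATA3 = 0.3),
        catalysts = "Tbet_g", k_back = 0.1, back_cat = "Prot",
        pre_name = "T-bet precursor pool", act_name = "T-bet")
  cycle("GATA3_pre", "GATA3", "transcription_factor", "STAT6_P",
        vmax = 0.4, km = 0.3, n = 2, inhibitors = c(Tbet = 0.3),
        catalysts = "GATA3_g", k_back = 0.1, back_cat = "Prot")
  cycle("RORgt_pre", "RORgt", "transcription_factor", "STAT3_P",
        vmax = 0.6, km = 0.25, n = 2,
        inhibitors = c(FOXP3 = 0.15, PPARg_a = 0.5, SMRT = 2),
        catalysts = c("RORgt_g", "SMAD3_P"),
        k_back = 0.04, back_cat = "Prot",
        pre_name = "RORgt precursor pool", act_name = "RORgt")
  cycle("FOXP3_pre", "FOXP3", "transcription_factor", "SMAD3_P",
        vmax = 0.8, km = 0.3, n = 2, inhibitors = c(STAT3_P = 0.05),
        catalysts = c("FOXP3_g", "PPARg_a"),
        k_back = 0.04, back_cat = "Prot")
  # Basal ligand tone PPARg_lig = 0.3 with km = 0.6 (n = 1) gives occupancy
  # 1/3, hence the naive steady state PPARg_a* = 0.25 used as initial level.
  cycle("PPARg", "PPARg_a", "transcription_factor", "PPARg_lig",
        vmax = 1, km = 0.6, n = 1,
        catalysts = c("PPARg_g", "RXR"), k_back = 1, back_cat = "Prot",
        init_pre = 0.75, init_act = 0.25,
        pre_name = "PPARg (apo)", act_name = "PPARg (ligand-activated)")

  # Signature-cytokine production cycles
  cycle("IFNg_pre", "IFNg_s", "secreted_cytokine", "Tbet",
        vmax = 0.8, km = 0.3, n = 2, inhibitors = c(GATA3 = 0.3),
        catalysts = c("IFNg_g", "STAT4_P"), k_back = 0.1,
        act_name = "secreted IFN-gamma")
  cycle("IL4_pre", "IL4_s", "secreted_cytokine", "GATA3",
        vmax = 0.6, km = 0.3, n = 2, inhibitors = c(Tbet = 0.3),
        catalysts = "IL4_g", k_back = 0.1, act_name = "secreted IL-4")
  cycle("IL17_pre", "IL17_s", "secreted_cytokine", "RORgt",
        vmax = 0.8, km = 0.3, n = 2,
        inhibitors = c(FOXP3 = 0.2, PPARg_a = 0.5, STAT5_P = 0.5),
        catalysts = c("IL17_g", "STAT3_P"), k_back = 0.1,
        act_name = "secreted IL-17")
  cycle("IL21_pre", "IL21_s", "secreted_cytokine", "STAT3_P",
        vmax = 0.4, km = 0.3, n = 2, catalysts = "IL21_g", k_back = 0.1,
        act_name = "secreted IL-21")
  cycle("TGFb_pre", "TGFb_s", "secreted_cytokine", "FOXP3",
        vmax = 0.4, km = 0.4, n = 2, catalysts = "TGFb_g", k_back = 0.1,
        act_name = "secreted TGF-beta")
  cycle("IL10_pre", "IL10_s", "secreted_cytokine", "FOXP3",
        vmax = 0.4, km = 0.4, n = 2, catalysts = "IL10_g", k_back = 0.1,
        act_name = "secreted IL-10")
  cycle("IL2_pre", "IL2_s", "secreted_cytokine", "Tbet",
        vmax = 0.4, km = 0.3, n = 2, inhibitors = c(FOXP3 = 0.3),
        catalysts = "IL2_g", k_back = 0.1, act_name = "secreted IL-2")

  define_model(
    species = do.call(rbind, sp),
    reactions = rx,
    parameters = par,
    metadata = list(
      model_id = "cd4-diff-v1",
      calibration = "recalibrated",
      expected_counts = c(species = 93, reactions = 52, odes = 60),
      neutralizers = c(aIFNg = "IFNg_e", aIL4 = "IL4_e")
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
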