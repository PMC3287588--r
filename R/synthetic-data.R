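## Generator for the curated algal core network fixture: a compartmentalized,
## elementally balanced toy model of Chlamydomonas-like primary metabolism
## (light reactions with linear and optional cyclic electron flow, Calvin
## cycle with RuBisCO oxygenation, mitochondrial glycolate dehydrogenase
## photorespiration, microbody glyoxylate cycle, gluconeogenesis to starch,
## plastidic glycolysis, pyruvate-ferredoxin oxidoreductase, ferredoxin
## hydrogenase, fermentative drains and biomass drains).

## Base chemical formulas (Hill notation, neutral forms; reduced electron
## carriers carry one extra H per electron so redox reactions balance).
CORE_FORMULAS <- c(
  photon = "",                      # massless
  co2 = "CO2", o2 = "O2", h2o = "H2O", h = "H", h2 = "H2",
  nh3 = "H3N", pi = "H3O4P", ppi = "H4O7P2",
  ac = "C2H4O2", accoa = "C23H38N7O17P3S", coa = "C21H36N7O16P3S",
  amp = "C10H14N5O7P", adp = "C10H15N5O10P2", atp = "C10H16N5O13P3",
  nad = "C21H27N7O14P2", nadh = "C21H28N7O14P2",
  nadp = "C21H28N7O17P3", nadph = "C21H29N7O17P3",
  q = "C59H90O4", qh2 = "C59H92O4",
  fdxox = "Fe2S2", fdxrd = "HFe2S2",
  glyclt = "C2H4O3", glx = "C2H2O3", pglyc = "C2H5O6P", glyct = "C3H6O4",
  pg3 = "C3H7O7P", rubp = "C5H12O11P2", gap = "C3H7O6P",
  g6p = "C6H13O9P", g1p = "C6H13O9P", adpglc = "C16H25N5O15P2",
  starch = "C6H10O5",
  pep = "C3H5O6P", pyr = "C3H4O3",
  succ = "C4H6O4", fum = "C4H4O4", mal = "C4H6O5", oaa = "C4H4O5",
  ala = "C3H7NO2", etoh = "C2H6O", acald = "C2H4O", lac = "C3H6O3",
  "for" = "CH2O2", h2o2 = "H2O2", hdca = "C16H32O2"
)

## Fixture energy parameters (documented assumptions, not literature values):
## photons per electron through linear flow (PSII+PSI), photons per ATP in
## cyclic flow, mitochondrial P/O ratios, growth- and non-growth-associated
## ATP maintenance.
CORE_PARAMS <- list(
  photons_per_fdx = 2,      # 8 photons : 4 reduced ferredoxin in linear flow
  lef_atp_per_o2 = 2,       # proton-gradient ATP per O2 evolved (lumped b6f)
  cef_photons_per_atp = 2,
  po_nadh = 2.5, po_qh2 = 1.5,
  gam_atp = 30,             # mmol ATP per gDW biomass
  ngam_atp = 0.1,           # mmol gDW^-1 h^-1 maintenance floor
  photon_cap = 200,         # uptake cap standing in for constant illumination
  uptake_cap = 10           # cap on CO2 / acetate / NH3 / Pi uptake
)

#' Generate the algal core network fixture
#'
#' Builds a compartmentalized, elementally balanced core model of algal
#' primary metabolism spanning cytosol, plastid, mitochondrion, microbody
#' and extracellular space. The default configuration is the canonical
#' fixture used throughout the test suite: it is deterministic and does
#' not depend on `random_seed`.
#'
#' Switches select between algal-style photorespiration (mitochondrial
#' glycolate dehydrogenase feeding the ubiquinone pool, and/or glycolate
#' secretion) and the plant-style peroxisomal route (glycolate oxidase +
#' catalase + recycling to glycerate), and include or drop cyclic electron
#' flow and the fermentative drains.
#'
#' @param include_cyclic_electron_flow include PSI cyclic electron flow
#'   (reduced ferredoxin + photons -> ATP).
#' @param include_glycolate_dehydrogenase include the algal mitochondrial
#'   glycolate dehydrogenase route.
#' @param include_plant_style_photorespiration include the plant-type
#'   microbody glycolate oxidase/catalase recycling path.
#' @param include_glycolate_secretion include glycolate export.
#' @param include_fermentation include the formate/ethanol/lactate drains.
#' @param random_seed kept for interface stability; the core network is
#'   seed-independent.
#' @return a `phyco_model` with four biomass component drains, a combined
#'   biomass equation, and metabolite formulas attached.
#' @export
generate_core_network <- function(include_cyclic_electron_flow = TRUE,
                                  include_glycolate_dehydrogenase = TRUE,
                                  include_plant_style_photorespiration = FALSE,
                                  include_glycolate_secretion = TRUE,
                                  include_fermentation = TRUE,
                                  random_seed = 1L) {
  p <- CORE_PARAMS
  rows <- list()
  rx <- function(id, eq, name = id, gpr = "", kind = "enzymatic",
                 ev = "literature", ss = "", lb = NULL, ub = NULL) {
    rows[[length(rows) + 1L]] <<- list(id = id, eq = eq, name = name,
                                       gpr = gpr, kind = kind, ev = ev,
                                       ss = ss, lb = lb, ub = ub)
  }

  ## -- exchanges (uptake = negative flux) ----------------------------------
  ex <- function(id, met, lb, ub, name) {
    rx(id, paste(met, "<=>"), name = name, kind = "exchange",
       ev = "not_applicable", ss = "exchange", lb = lb, ub = ub)
  }
  ex("EX_photon", "photon_e", -p$photon_cap, 0, "photon uptake")
  ex("EX_co2", "co2_e", -p$uptake_cap, FLUX_BOUND, "CO2 exchange")
  ex("EX_o2", "o2_e", -FLUX_BOUND, FLUX_BOUND, "O2 exchange")
  ex("EX_h2o", "h2o_e", -FLUX_BOUND, FLUX_BOUND, "water exchange")
  ex("EX_h", "h_e", -FLUX_BOUND, FLUX_BOUND, "proton exchange")
  ex("EX_nh3", "nh3_e", -p$uptake_cap, FLUX_BOUND, "ammonia exchange")
  ex("EX_pi", "pi_e", -p$uptake_cap, FLUX_BOUND, "phosphate exchange")
  ex("EX_ac", "ac_e", -p$uptake_cap, FLUX_BOUND, "acetate exchange")
  ex("EX_h2", "h2_e", 0, FLUX_BOUND, "hydrogen secretion")
  if (include_glycolate_secretion)
    ex("EX_glyclt", "glyclt_e", 0, FLUX_BOUND, "glycolate secretion")
  if (include_fermentation) {
    ex("EX_for", "for_e", 0, FLUX_BOUND, "formate secretion")
    ex("EX_etoh", "etoh_e", 0, FLUX_BOUND, "ethanol secretion")
    ex("EX_lac", "lac_e", 0, FLUX_BOUND, "lactate secretion")
  }

  ## -- transporters --------------------------------------------------------
  tr <- function(id, eq, name, ev = "literature") {
    rx(id, eq, name = name, kind = "transport", ev = ev, ss = "transport")
  }
  tr("t_photon_ep", "photon_e --> photon_p", "photon capture (antenna)")
  for (cp in c("ec", "cp", "cm")) {
    a <- substr(cp, 1, 1); b <- substr(cp, 2, 2)
    tr(paste0("t_co2_", cp), sprintf("co2_%s <=> co2_%s", a, b),
       paste("CO2 diffusion", cp))
  }
  tr("t_co2_cx", "co2_c <=> co2_x", "CO2 diffusion cx")
  for (cp in c("ec", "cp", "cm", "cx")) {
    a <- substr(cp, 1, 1); b <- substr(cp, 2, 2)
    tr(paste0("t_o2_", cp), sprintf("o2_%s <=> o2_%s", a, b),
       paste("O2 diffusion", cp))
    tr(paste0("t_h2o_", cp), sprintf("h2o_%s <=> h2o_%s", a, b),
       paste("water diffusion", cp))
    tr(paste0("t_h_", cp), sprintf("h_%s <=> h_%s", a, b),
       paste("proton transport", cp))
    tr(paste0("t_pi_", cp), sprintf("pi_%s <=> pi_%s", a, b),
       paste("phosphate transport", cp))
  }
  tr("t_nh3_ec", "nh3_e <=> nh3_c", "ammonia uptake")
  tr("t_ac_ec", "ac_e <=> ac_c", "acetate uptake")
  tr("t_ac_cx", "ac_c <=> ac_x", "acetate transport to microbody")
  tr("t_ac_pc", "ac_p <=> ac_c", "plastid acetate export")
  tr("t_glyclt_pc", "glyclt_p <=> glyclt_c", "glycolate export from plastid")
  if (include_glycolate_dehydrogenase)
    tr("t_glyclt_cm", "glyclt_c <=> glyclt_m", "glycolate import, mitochondrion")
  if (include_glycolate_secretion)
    tr("t_glyclt_ce", "glyclt_c <=> glyclt_e", "glycolate secretion")
  if (include_plant_style_photorespiration) {
    tr("t_glyclt_cx", "glyclt_c <=> glyclt_x", "glycolate import, microbody",
       ev = "homolog")
    tr("t_glyct_xc", "glyct_x <=> glyct_c", "glycerate export", ev = "homolog")
    tr("t_glyct_cp", "glyct_c <=> glyct_p", "glycerate import, plastid",
       ev = "homolog")
  }
  tr("t_h2_pc", "h2_p <=> h2_c", "H2 diffusion pc")
  tr("t_h2_ce", "h2_c <=> h2_e", "H2 diffusion ce")
  if (include_fermentation) {
    tr("t_for_ce", "for_c --> for_e", "formate export")
    tr("t_etoh_ce", "etoh_c --> etoh_e", "ethanol export")
    tr("t_lac_ce", "lac_c --> lac_e", "lactate export")
  }
  tr("t_succ_xm", "succ_x --> succ_m", "succinate transporter")
  tr("t_oaa_mc", "oaa_m <=> oaa_c", "oxaloacetate transporter")
  tr("t_pyr_cm", "pyr_c <=> pyr_m", "pyruvate transporter")
  tr("t_accoa_cm", "accoa_c + coa_m <=> coa_c + accoa_m",
     "acetyl unit shuttle (carnitine-type, lumped)")
  tr("t_g6p_cp", "g6p_c <=> g6p_p", "glucose 6-phosphate translocator")
  tr("t_atp_cp", "atp_c + adp_p <=> adp_c + atp_p", "ATP/ADP translocator cp")
  tr("t_atp_cm", "atp_m + adp_c <=> adp_m + atp_c", "ATP/ADP translocator cm")
  tr("t_atp_cx", "atp_c + adp_x <=> adp_c + atp_x", "ATP/ADP translocator cx")
  tr("t_nadh_cm", "nadh_c + nad_m <=> nad_c + nadh_m",
     "malate-aspartate shuttle (lumped)")
  tr("t_nadh_pc", "nadh_p + nad_c <=> nad_p + nadh_c",
     "plastid malate valve (lumped)")
  tr("t_nadh_xc", "nadh_x + nad_c <=> nad_x + nadh_c",
     "microbody redox shuttle (lumped)")

  ## -- plastid: light reactions, Calvin cycle, starch, glycolysis, H2 ------
  rx("lef", sprintf(
    "%d photon_p + 4 fdxox_p + %d adp_p + %d pi_p --> o2_p + 4 fdxrd_p + %d atp_p",
    4 * p$photons_per_fdx, p$lef_atp_per_o2, p$lef_atp_per_o2,
    p$lef_atp_per_o2),
    "linear electron flow (PSII+b6f+PSI, lumped photophosphorylation)",
    gpr = "PSBA and PSAA", ss = "light reactions")
  if (include_cyclic_electron_flow)
    rx("cef", sprintf(
      "%d photon_p + 2 fdxrd_p + adp_p + pi_p --> 2 fdxox_p + atp_p + h2o_p + 2 h_p",
      p$cef_photons_per_atp),
      "cyclic electron flow (PSI, lumped)", gpr = "PGRL1",
      ss = "light reactions")
  rx("fnr", "2 fdxrd_p + nadp_p --> 2 fdxox_p + nadph_p + h_p",
     "ferredoxin-NADP+ reductase", gpr = "FNR1", ss = "light reactions")
  rx("hyda", "2 fdxrd_p --> 2 fdxox_p + h2_p",
     "ferredoxin hydrogenase", gpr = "HYDA1 or HYDA2",
     ss = "hydrogen production")
  rx("pfr", "pyr_p + coa_p + 2 fdxox_p --> accoa_p + co2_p + 2 fdxrd_p",
     "pyruvate-ferredoxin oxidoreductase", gpr = "PFR1", ss = "fermentation")
  rx("rbc_c", "rubp_p + co2_p + h2o_p --> 2 pg3_p",
     "RuBisCO carboxylation", gpr = "rbcL and RBCS1", ss = "calvin cycle")
  rx("rbc_o", "rubp_p + o2_p --> pg3_p + pglyc_p",
     "RuBisCO oxygenation", gpr = "rbcL and RBCS1", ss = "photorespiration")
  rx("calvin_regen", "5 gap_p + 3 atp_p + 2 h2o_p --> 3 rubp_p + 3 adp_p + 2 pi_p",
     "RuBP regeneration (lumped)", gpr = "PRK1 and TRK1", ss = "calvin cycle")
  rx("gap_red", "pg3_p + atp_p + nadph_p + h_p --> gap_p + adp_p + pi_p + nadp_p",
     "phosphoglycerate reduction (NADP-GAPDH, lumped)", gpr = "GAP1",
     ss = "calvin cycle")
  rx("pgp", "pglyc_p + h2o_p --> glyclt_p + pi_p",
     "phosphoglycolate phosphatase", gpr = "PGP1", ss = "photorespiration")
  rx("fba_p", "2 gap_p + h2o_p --> g6p_p + pi_p",
     "plastid gluconeogenesis to G6P (lumped)", gpr = "FBA3 and FBP1",
     ss = "gluconeogenesis")
  rx("pfk_p", "g6p_p + atp_p --> 2 gap_p + adp_p",
     "plastid phosphofructokinase (lumped)", gpr = "PFK1",
     ss = "glycolysis (plastidic)")
  rx("gapdh_p", "gap_p + nad_p + pi_p + adp_p --> pep_p + nadh_p + h_p + atp_p + h2o_p",
     "glyceraldehyde-3-phosphate dehydrogenase, glycolytic (lumped to PEP)",
     gpr = "GAP3", ss = "glycolysis (plastidic)")
  rx("pyk_p", "pep_p + adp_p --> pyr_p + atp_p",
     "plastid pyruvate kinase", gpr = "PYK1", ss = "glycolysis (plastidic)")
  rx("oxppp_p", "g6p_p + 12 nadp_p + 7 h2o_p --> 6 co2_p + 12 nadph_p + pi_p + 12 h_p",
     "oxidative pentose phosphate pathway (lumped to CO2)",
     gpr = "G6PD1 and PGL1 and GND1", ev = "homolog",
     ss = "pentose phosphate pathway (plastidic)")
  rx("pgm_p", "g6p_p <=> g1p_p", "phosphoglucomutase", gpr = "PGM1",
     ev = "homolog", ss = "starch synthesis")
  rx("agp", "g1p_p + atp_p --> adpglc_p + ppi_p",
     "ADP-glucose pyrophosphorylase", gpr = "STA1 and STA6",
     ss = "starch synthesis")
  rx("ss", "adpglc_p --> starch_p + adp_p",
     "starch synthase + branching enzyme", gpr = "STA2 and SBE1",
     ss = "starch synthesis")
  rx("ppa_p", "ppi_p + h2o_p --> 2 pi_p", "plastid pyrophosphatase",
     gpr = "PPA1", ev = "homolog", ss = "starch synthesis")
  rx("palm", paste("8 accoa_p + 7 atp_p + 14 nadph_p + 14 h_p + h2o_p -->",
                   "hdca_p + 8 coa_p + 7 adp_p + 7 pi_p + 14 nadp_p"),
     "palmitate synthesis (lumped)", gpr = "FAS1", ss = "fatty acid synthesis")
  rx("ack_p", "accoa_p + adp_p + pi_p --> ac_p + atp_p + coa_p",
     "phosphotransacetylase + acetate kinase", gpr = "PAT2 and ACK2",
     ss = "fermentation")

  ## -- mitochondrion: glycolate oxidation, TCA, oxidative phosphorylation --
  if (include_glycolate_dehydrogenase)
    rx("gld", "glyclt_m + q_m --> glx_m + qh2_m",
       "glycolate dehydrogenase (ubiquinone-linked)", gpr = "GYD1",
       ss = "photorespiration")
  rx("gap_ms_m", "glx_m + accoa_m + h2o_m --> mal_m + coa_m",
     "mitochondrial malate synthase (curation gap)", kind = "non_enzymatic_gap",
     ev = "not_applicable", ss = "photorespiration")
  rx("sdh", "succ_m + q_m --> fum_m + qh2_m",
     "succinate dehydrogenase", gpr = "SDH1", ss = "acetate assimilation")
  rx("fumarase", "fum_m + h2o_m <=> mal_m", "fumarase", gpr = "FUM1",
     ss = "acetate assimilation")
  rx("mdh_m", "mal_m + nad_m <=> oaa_m + nadh_m + h_m",
     "malate dehydrogenase", gpr = "MDH1", ss = "acetate assimilation")
  rx("pdh_m", "pyr_m + coa_m + nad_m --> accoa_m + co2_m + nadh_m + h_m",
     "pyruvate dehydrogenase complex", gpr = "PDH1 and DLA1", ss = "TCA cycle")
  rx("tca", paste("accoa_m + 3 nad_m + q_m + adp_m + pi_m + 2 h2o_m -->",
                  "2 co2_m + coa_m + 3 nadh_m + qh2_m + atp_m + 3 h_m"),
     "TCA cycle, citrate to oxaloacetate (lumped)",
     gpr = "CIS2 and ACH1 and IDH2 and OGD1 and MDH2", ss = "TCA cycle")
  rx("etc_nadh", sprintf(
    "nadh_m + h_m + 0.5 o2_m + %.1f adp_m + %.1f pi_m --> nad_m + %.1f atp_m + %.1f h2o_m",
    p$po_nadh, p$po_nadh, p$po_nadh, p$po_nadh + 1),
    "NADH respiration + ATP synthase (lumped)", gpr = "NUO1 and COX1 and ATP2",
    ss = "oxidative phosphorylation")
  rx("etc_qh2", sprintf(
    "qh2_m + 0.5 o2_m + %.1f adp_m + %.1f pi_m --> q_m + %.1f atp_m + %.1f h2o_m",
    p$po_qh2, p$po_qh2, p$po_qh2, p$po_qh2 + 1),
    "ubiquinol respiration + ATP synthase (lumped)", gpr = "COX1 and ATP2",
    ss = "oxidative phosphorylation")

  ## -- microbody: acetate activation and glyoxylate cycle ------------------
  rx("acs_x", "ac_x + atp_x + coa_x --> accoa_x + amp_x + ppi_x",
     "acetyl-CoA synthetase (microbody)", gpr = "ACS1", ss = "glyoxylate cycle")
  rx("glyox_cycle", "2 accoa_x + nad_x + 2 h2o_x --> succ_x + 2 coa_x + nadh_x + h_x",
     "glyoxylate cycle, two acetyl-CoA to succinate (lumped)",
     gpr = "ICL1 and MAS1", ss = "glyoxylate cycle")
  rx("gap_ppa_x", "ppi_x + h2o_x --> 2 pi_x",
     "microbody pyrophosphatase (curation gap)", kind = "non_enzymatic_gap",
     ev = "not_applicable", ss = "glyoxylate cycle")
  rx("gap_adk_x", "amp_x + atp_x <=> 2 adp_x",
     "microbody adenylate kinase (curation gap)", kind = "non_enzymatic_gap",
     ev = "not_applicable", ss = "glyoxylate cycle")
  if (include_plant_style_photorespiration) {
    rx("gox_x", "glyclt_x + o2_x --> glx_x + h2o2_x",
       "glycolate oxidase", gpr = "GOX1", ev = "homolog",
       ss = "photorespiration (plant-type)")
    rx("cat_x", "2 h2o2_x --> 2 h2o_x + o2_x", "catalase", gpr = "CAT1",
       ev = "homolog", ss = "photorespiration (plant-type)")
    rx("glx2glyct_x", "2 glx_x + nadh_x + h_x --> glyct_x + co2_x + nad_x",
       "glyoxylate to glycerate (transaminase/reductase, lumped)",
       gpr = "SGA1 and HPR1", ev = "homolog",
       ss = "photorespiration (plant-type)")
    rx("glyck_p", "glyct_p + atp_p --> pg3_p + adp_p", "glycerate kinase",
       gpr = "GLYK1", ev = "homolog", ss = "photorespiration (plant-type)")
  }

  ## -- cytosol: acetate activation, gluconeogenesis, glycolysis,
  ##    biosynthesis, fermentation, maintenance ----------------------------
  rx("acs_c", "ac_c + atp_c + coa_c --> accoa_c + amp_c + ppi_c",
     "acetyl-CoA synthetase (cytosol)", gpr = "ACS2", ss = "acetate assimilation")
  rx("ppa_c", "ppi_c + h2o_c --> 2 pi_c", "cytosolic pyrophosphatase",
     gpr = "PPA2", ev = "homolog", ss = "acetate assimilation")
  rx("adk_c", "amp_c + atp_c <=> 2 adp_c", "adenylate kinase", gpr = "ADK1",
     ev = "homolog", ss = "nucleotide metabolism")
  rx("pepck", "oaa_c + atp_c --> pep_c + co2_c + adp_c",
     "phosphoenolpyruvate carboxykinase", gpr = "PCK1", ss = "gluconeogenesis")
  rx("gluconeo_c", paste(
    "2 pep_c + 2 atp_c + 2 nadh_c + 2 h_c + 3 h2o_c -->",
    "g6p_c + 2 adp_c + 3 pi_c + 2 nad_c"),
    "gluconeogenesis PEP to G6P (lumped)", gpr = "ENO1 and FBP1",
    ss = "gluconeogenesis")
  rx("pfk_c", "g6p_c + atp_c --> 2 gap_c + adp_c",
     "cytosolic phosphofructokinase (lumped)", gpr = "PFK2",
     ev = "homolog", ss = "glycolysis (cytosolic)")
  rx("gapdh_c", "gap_c + nad_c + pi_c + adp_c --> pep_c + nadh_c + h_c + atp_c + h2o_c",
     "glyceraldehyde-3-phosphate dehydrogenase, glycolytic (lumped to PEP)",
     gpr = "GAP2", ev = "homolog", ss = "glycolysis (cytosolic)")
  rx("pyk_c", "pep_c + adp_c --> pyr_c + atp_c",
     "cytosolic pyruvate kinase", gpr = "PYK2", ev = "homolog",
     ss = "glycolysis (cytosolic)")
  rx("alats", "pyr_c + nh3_c + nadh_c + h_c --> ala_c + nad_c + h2o_c",
     "alanine synthesis (reductive amination, lumped)", gpr = "AAT1",
     ev = "homolog", ss = "amino acid synthesis")
  rx("amps", paste("2 g6p_c + 5 nh3_c + 4 atp_c + h2o_c -->",
                   "amp_c + 2 co2_c + 4 adp_c + 5 pi_c + 18 h_c"),
     "AMP de novo synthesis (lumped)", gpr = "ADE1 and ADE2", ev = "homolog",
     ss = "nucleotide metabolism")
  if (include_fermentation) {
    rx("pfl", "pyr_c + coa_c --> accoa_c + for_c",
       "pyruvate formate lyase", gpr = "PFL1", ev = "default_cytosol",
       ss = "fermentation")
    rx("pdc", "pyr_c --> acald_c + co2_c", "pyruvate decarboxylase",
       gpr = "PDC3", ev = "default_cytosol", ss = "fermentation")
    rx("adh", "acald_c + nadh_c + h_c --> etoh_c + nad_c",
       "alcohol dehydrogenase", gpr = "ADH1", ev = "default_cytosol",
       ss = "fermentation")
    rx("ldh", "pyr_c + nadh_c + h_c --> lac_c + nad_c",
       "lactate dehydrogenase", gpr = "LDH1", ev = "default_cytosol",
       ss = "fermentation")
  }
  rx("atpm", "atp_c + h2o_c --> adp_c + pi_c",
     "non-growth-associated maintenance", ss = "maintenance",
     lb = p$ngam_atp, ub = FLUX_BOUND)

  ## -- biomass component drains -------------------------------------------
  dm <- function(id, met, name) {
    rx(id, paste(met, "-->"), name = name, kind = "biomass_drain",
       ev = "not_applicable", ss = "biomass")
  }
  dm("dm_starch", "starch_p", "starch drain")
  dm("dm_ala", "ala_c", "alanine drain")
  dm("dm_amp", "amp_c", "AMP drain")
  dm("dm_hdca", "hdca_p", "palmitate drain")

  ## -- assemble ------------------------------------------------------------
  rxns <- vector("list", length(rows))
  met_ids <- character(0)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    eq <- parse_equation(r$eq)
    lb <- if (!is.null(r$lb)) r$lb else if (eq$reversible) -FLUX_BOUND else 0
    ub <- if (!is.null(r$ub)) r$ub else FLUX_BOUND
    rxns[[i]] <- reaction(r$id, eq$stoich, name = r$name,
                          reversible = eq$reversible, lb = lb, ub = ub,
                          gpr = r$gpr, kind = r$kind, evidence = r$ev,
                          subsystem = r$ss)
    met_ids <- union(met_ids, names(eq$stoich))
  }
  mets <- do.call(rbind, lapply(sort(met_ids), function(id) {
    base <- sub("_[cpmxe]$", "", id)
    metabolite(id, formula = unname(CORE_FORMULAS[base]),
               is_boundary = endsWith(id, "_e"))
  }))
  model <- phyco_model(mets, rxns,
                       biomass_components = c("dm_starch", "dm_ala",
                                              "dm_amp", "dm_hdca"))
  add_biomass_equation(model, core_biomass_composition())
}

#' Default biomass composition of the core fixture
#'
#' Documented fixture coefficients (mmol per gDW): starch glucosyl units
#' 10, alanine 5, AMP 1, palmitate 0.5, plus 30 mmol growth-associated ATP
#' hydrolysis. These are order-of-magnitude algal values chosen for the
#' fixture, not literature measurements.
#'
#' @param condition trophic label recorded on the composition.
#' @return a [biomass_composition()].
#' @export
core_biomass_composition <- function(condition = "mixotrophic") {
  biomass_composition(
    c(starch_p = 10, ala_c = 5, amp_c = 1, hdca_p = 0.5),
    condition = condition,
    atp_maintenance = CORE_PARAMS$gam_atp
  )
}

#' Seed gaps into a model for gap-analysis testing
#'
#' Deterministically deletes `n` internal (non-exchange, non-biomass)
#' reactions, preferring reactions that are the sole producer of some
#' metabolite so that the seeded gaps are detectable, and returns the
#' ground truth.
#'
#' @param model a `phyco_model`.
#' @param n number of reactions to delete.
#' @param seed integer seed controlling the choice.
#' @return list with `model` (the gapped model) and `deleted` (ids).
#' @export
seed_gaps <- function(model, n = 1L, seed = 1L) {
  kinds <- vapply(model$reactions, `[[`, "", "kind")
  candidates <- names(kinds)[!kinds %in% c("exchange", "biomass_drain")]
  if (n >= length(candidates))
    stop("cannot seed ", n, " gaps: only ", length(candidates),
         " removable reactions", call. = FALSE)
  ## reactions that are the sole possible producer of some metabolite
  S <- stoichiometric_matrix(model)
  rev <- vapply(model$reactions[colnames(S)], function(r) r$lb < 0, TRUE)
  can_produce <- (S > 0) | (S != 0 & rep(rev, each = nrow(S)))
  producers_per_met <- rowSums(can_produce)
  sole <- character(0)
  for (i in which(producers_per_met == 1))
    sole <- union(sole, colnames(S)[which(can_produce[i, ])])
  sole <- intersect(sole, candidates)
  other <- setdiff(candidates, sole)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- if (n <= length(sole)) sample(sole, n)
  else c(sample(sole), sample(other, n - length(sole)))
  model$reactions[pick] <- NULL
  ## drop metabolites no longer referenced by any reaction
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ]
  model$biomass_components <- intersect(model$biomass_components,
                                        names(model$reactions))
  list(model = validate_model(model), deleted = sort(pick))
}

#' Export the core fixture as raw curation tables
#'
#' Writes the tab-delimited reaction, formula, evidence and transporter
#' tables from which the reconstruction pipeline can rebuild the fixture
#' end-to-end, plus the SBML serialization.
#'
#' @param model a `phyco_model` (default: the canonical fixture).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture_tables <- function(model = generate_core_network(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reaction_table(model, file.path(dir, "reactions.tsv"))
  write_formula_table(
    stats::setNames(model$metabolites$formula, model$metabolites$id),
    file.path(dir, "formulas.tsv"))
  ev <- vapply(model$reactions, `[[`, "", "evidence")
  keep <- ev %in% c("literature", "homolog")
  comp1 <- vapply(model$reactions[keep], function(r)
    met_compartment(model, names(r$stoich)[1]), "")
  utils::write.table(
    data.frame(reaction_id = names(model$reactions)[keep],
               compartment = unname(comp1), source = unname(ev[keep]),
               citation = "fixture", stringsAsFactors = FALSE),
    file.path(dir, "evidence.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_sbml(model, file.path(dir, "model.xml"))
  invisible(dir)
}
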