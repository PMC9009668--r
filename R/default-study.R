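#' Default study conditions: a three-city Mexican fish market survey
#'
#' `default_study_pool()`, `default_study_design()` and
#' `default_study_catalogs()` encode the conditions of a 2018 market survey
#' of fish sold in Mazatlan, Mexico City and Cancun: 376 analyzable samples
#' purchased under 48 commercial names (plus 7 samples under the generic
#' name "pescado"), drawn from a pool of roughly a hundred species with a
#' heavy-tailed supply spectrum in which five globally traded species
#' (yellowfin tuna, Atlantic salmon, mahi mahi, tilapia, swai) dominate.
#' The 18 focal names carry their observed verbal sample counts and
#' mislabeling rates as the true per-name mislabeling probabilities; the 30
#' rare names share the residual rate (17 mislabels over 60 samples).
#'
#' @name default-study
NULL

# genus -> category lookup used when assembling the default pool
AQUA_GENERA <- c(
  "Salmo", "Oncorhynchus", "Oreochromis", "Pangasianodon", "Cyprinus",
  "Ctenopharyngodon", "Hypophthalmichthys", "Ictalurus", "Anguilla"
)
ELASMO_GENERA <- c(
  "Carcharhinus", "Sphyrna", "Prionace", "Mustelus", "Alopias", "Dasyatis",
  "Rhizoprionodon", "Galeocerdo", "Isurus", "Pseudobatos"
)

default_species_list <- function() {
  # five globally traded species first: they take the top supply ranks
  c(
    "Thunnus albacares", "Salmo salar", "Coryphaena hippurus",
    "Oreochromis niloticus", "Pangasianodon hypophthalmus",
    "Thunnus obesus", "Thunnus orientalis", "Katsuwonus pelamis",
    "Oncorhynchus mykiss", "Oncorhynchus kisutch", "Oreochromis aureus",
    "Epinephelus morio", "Epinephelus itajara", "Epinephelus labriformis",
    "Epinephelus analogum", "Mycteroperca bonaci", "Mycteroperca rosacea",
    "Hyporthodus acanthistius", "Hyporthodus niphobles",
    "Lutjanus peru", "Lutjanus campechanus", "Lutjanus argentiventris",
    "Lutjanus griseus", "Lutjanus guttatus", "Lutjanus synagris",
    "Lutjanus vivanus", "Lutjanus colorado", "Lutjanus novemfasciatus",
    "Centropomus viridis", "Centropomus undecimalis", "Centropomus robalito",
    "Cynoscion othonopterus", "Cynoscion reticulatus", "Cynoscion parvipinnis",
    "Cynoscion nebulosus", "Scomberomorus sierra", "Scomberomorus maculatus",
    "Scomberomorus concolor", "Seriola lalandi", "Seriola rivoliana",
    "Caranx caninus", "Caranx hippos", "Caranx sexfasciatus",
    "Pagrus pagrus", "Paralichthys californicus", "Paralichthys lethostigma",
    "Istiophorus platypterus", "Makaira nigricans", "Kajikia audax",
    "Nematistius pectoralis", "Sarda orientalis", "Lachnolaimus maximus",
    "Lopholatilus chamaeleonticeps", "Merluccius productus",
    "Merluccius gayi", "Peprilus snyderi", "Peprilus paru",
    "Mugil cephalus", "Mugil curema", "Gerres cinereus",
    "Eugerres plumieri", "Eugerres axillaris", "Calamus brachysomus",
    "Haemulon plumierii", "Haemulon flaviguttatum", "Balistes polylepis",
    "Balistes capriscus", "Sphoeroides annulatus", "Sciades seemanni",
    "Ariopsis felis", "Bagre panamensis", "Acanthocybium solandri",
    "Trachinotus paitensis", "Sphyraena barracuda", "Sphyraena ensis",
    "Totoaba macdonaldi", "Micropogonias undulatus", "Umbrina xanti",
    "Anisotremus interruptus", "Diplectrum pacificum", "Kyphosus vaigiensis",
    "Rachycentron canadum", "Xiphias gladius", "Stereolepis gigas",
    "Scorpaena guttata", "Caulolatilus princeps",
    # elasmobranchs
    "Carcharhinus falciformis", "Carcharhinus leucas", "Carcharhinus limbatus",
    "Carcharhinus plumbeus", "Carcharhinus acronotus", "Carcharhinus brevipinna",
    "Sphyrna lewini", "Sphyrna zygaena", "Prionace glauca", "Mustelus canis",
    "Mustelus californicus", "Alopias pelagicus", "Dasyatis americana",
    "Dasyatis dipterura", "Rhizoprionodon terraenovae", "Pseudobatos productus",
    # aquaculture / freshwater
    "Cyprinus carpio", "Ctenopharyngodon idella", "Hypophthalmichthys molitrix",
    "Ictalurus punctatus", "Anguilla anguilla", "Anguilla rostrata",
    # rare tail: species available to the market at low supply, mostly seen
    # (if at all) a single time as substitutes or under rare names
    "Lutjanus aratus", "Lutjanus jordani", "Lutjanus inermis",
    "Epinephelus cifuentesi", "Epinephelus quinquefasciatus",
    "Epinephelus adscensionis", "Mycteroperca xenarcha",
    "Mycteroperca jordani", "Mycteroperca venenosa",
    "Cynoscion squamipinnis", "Cynoscion albus", "Cynoscion xanthulus",
    "Centropomus medius", "Centropomus nigrescens",
    "Caranx caballus", "Caranx latus", "Caranx crysos",
    "Seriola dumerili", "Seriola peruana",
    "Scomberomorus regalis", "Scomberomorus brasiliensis",
    "Haemulon sexfasciatum", "Haemulon scudderii", "Haemulon steindachneri",
    "Anisotremus virginicus", "Anisotremus davidsonii",
    "Gerres simillimus", "Eugerres lineatus",
    "Mugil hospes", "Mugil setosus",
    "Paralichthys woolmani", "Paralichthys aestuarius",
    "Merluccius angustimanus", "Merluccius bilinearis",
    "Peprilus medius", "Peprilus triacanthus",
    "Calamus penna", "Calamus nodosus",
    "Sphyraena lucasana", "Sphyraena argentea",
    "Balistes vetula", "Sphoeroides lobatus", "Kyphosus elegans",
    "Umbrina roncador", "Umbrina dorsalis", "Micropogonias megalops",
    "Diplectrum labarum", "Trachinotus rhodopus", "Trachinotus kennedyi",
    "Sarda chiliensis", "Bagre pinnimaculatus", "Ariopsis guatemalensis",
    "Sciades dowii", "Pomadasys panamensis", "Cephalopholis panamensis",
    "Hoplopagrus guentherii", "Opisthonema libertate",
    "Istiompax indica", "Tetrapturus angustirostris",
    "Scorpaena mystes", "Caulolatilus affinis",
    "Carcharhinus obscurus", "Carcharhinus porosus", "Sphyrna mokarran",
    "Mustelus henlei", "Alopias vulpinus", "Dasyatis longa",
    "Galeocerdo cuvier", "Isurus oxyrinchus", "Rhizoprionodon longurio",
    "Oreochromis mossambicus", "Oncorhynchus tshawytscha"
  )
}

#' @rdname default-study
#' @param zipf_exponent Decay exponent of the rank-based supply weights
#'   (`weight ~ rank^-exponent`); the default reproduces a spectrum in which
#'   about half of the observed species are singletons.
#' @export
default_study_pool <- function(zipf_exponent = 1.3) {
  sp <- default_species_list()
  genus <- genus_token(sp)
  category <- ifelse(genus %in% AQUA_GENERA, "aquaculture_freshwater",
    ifelse(genus %in% ELASMO_GENERA, "elasmobranch", "marine_bony")
  )
  species_pool(tibble::tibble(
    species = sp,
    category = category,
    supply_weight = seq_along(sp)^(-zipf_exponent)
  ))
}

# commercial name -> accepted species, as a plain two-column data frame
default_name_map <- function() {
  m <- list(
    atun = c(
      "Thunnus albacares", "Thunnus obesus", "Thunnus orientalis",
      "Katsuwonus pelamis"
    ),
    salmon = c("Salmo salar", "Oncorhynchus kisutch"),
    cazon = c(
      "Mustelus canis", "Mustelus californicus",
      "Rhizoprionodon terraenovae", "Prionace glauca",
      "Carcharhinus falciformis", "Carcharhinus leucas",
      "Carcharhinus brevipinna", "Carcharhinus plumbeus",
      "Carcharhinus acronotus", "Sphyrna lewini", "Sphyrna zygaena"
    ),
    dorado = "Coryphaena hippurus",
    marlin = c("Makaira nigricans", "Kajikia audax"),
    tilapia = c("Oreochromis niloticus", "Oreochromis aureus"),
    mero = c(
      "Epinephelus morio", "Epinephelus itajara", "Mycteroperca bonaci",
      "Mycteroperca rosacea"
    ),
    robalo = c(
      "Centropomus viridis", "Centropomus undecimalis", "Centropomus robalito"
    ),
    mojarra = c(
      "Gerres cinereus", "Eugerres plumieri", "Eugerres axillaris",
      "Calamus brachysomus"
    ),
    huachinango = c(
      "Lutjanus peru", "Lutjanus campechanus", "Lutjanus colorado"
    ),
    basa = "Pangasianodon hypophthalmus",
    pargo = c(
      "Lutjanus argentiventris", "Lutjanus griseus", "Lutjanus guttatus",
      "Lutjanus novemfasciatus"
    ),
    sierra = c("Scomberomorus sierra", "Scomberomorus maculatus"),
    curvina = c(
      "Cynoscion othonopterus", "Cynoscion reticulatus",
      "Cynoscion nebulosus"
    ),
    cochito = c("Balistes polylepis", "Balistes capriscus"),
    lenguado = c("Paralichthys californicus", "Paralichthys lethostigma"),
    peto = "Acanthocybium solandri",
    trucha = "Oncorhynchus mykiss",
    # rare names
    sardina = "Sarda orientalis",
    lisa = c("Mugil cephalus", "Mugil curema"),
    jurel = c("Caranx caninus", "Caranx hippos", "Caranx sexfasciatus"),
    cabrilla = c("Epinephelus labriformis", "Epinephelus analogum"),
    extraviado = "Hyporthodus acanthistius",
    boquinete = "Lachnolaimus maximus",
    blanco = "Lopholatilus chamaeleonticeps",
    villajaiba = "Lutjanus synagris",
    rubia = "Lutjanus vivanus",
    anguila = c("Anguilla anguilla", "Anguilla rostrata"),
    mantarraya = c("Dasyatis americana", "Dasyatis dipterura"),
    guitarra = "Pseudobatos productus",
    tiburon = c("Prionace glauca", "Carcharhinus falciformis"),
    esmedregal = "Rachycentron canadum",
    pampano = "Trachinotus paitensis",
    barracuda = c("Sphyraena barracuda", "Sphyraena ensis"),
    corvineta = "Umbrina xanti",
    berrugata = "Micropogonias undulatus",
    chihuil = "Bagre panamensis",
    bandera = "Sciades seemanni",
    merluza = c("Merluccius productus", "Merluccius gayi"),
    palometa = c("Peprilus snyderi", "Peprilus paru"),
    botete = "Sphoeroides annulatus",
    burro = "Anisotremus interruptus",
    chopa = "Kyphosus vaigiensis",
    carpa = c("Cyprinus carpio", "Ctenopharyngodon idella"),
    bagre = c("Ictalurus punctatus", "Ariopsis felis"),
    "pez espada" = "Xiphias gladius",
    jurelillo = "Seriola lalandi",
    baqueta = "Hyporthodus niphobles"
  )
  tibble::tibble(
    commercial_name = rep(names(m), lengths(m)),
    species = unlist(m, use.names = FALSE)
  )
}

#' @rdname default-study
#' @details The three catalogs share union semantics: the first holds the
#'   full name-to-species mapping while the other two are deterministic
#'   partial copies, so a species may be accepted in only one catalog.
#' @export
default_study_catalogs <- function() {
  map <- default_name_map()
  n <- nrow(map)
  list(
    catalog("pacifico", map),
    catalog("nacional", map[seq_len(n) %% 4L != 0L, ]),
    catalog("global", map[seq_len(n) %% 3L != 0L, ])
  )
}

# verbal sample counts of the 18 focal names (316 samples) and their
# observed mislabeling rates, used as the true per-name probabilities
FOCAL_NAME_COUNTS <- c(
  atun = 58L, salmon = 39L, cazon = 32L, dorado = 31L, marlin = 18L,
  tilapia = 18L, mero = 15L, robalo = 15L, mojarra = 15L, huachinango = 13L,
  basa = 12L, pargo = 11L, sierra = 9L, curvina = 6L, cochito = 6L,
  lenguado = 6L, peto = 6L, trucha = 6L
)
FOCAL_NAME_MISLABEL_COUNTS <- c(
  atun = 6L, salmon = 2L, cazon = 3L, dorado = 12L, marlin = 17L,
  tilapia = 2L, mero = 13L, robalo = 8L, mojarra = 6L, huachinango = 7L,
  basa = 0L, pargo = 4L, sierra = 8L, curvina = 3L, cochito = 2L,
  lenguado = 2L, peto = 2L, trucha = 2L
)

#' @rdname default-study
#' @export
default_study_design <- function() {
  rare_names <- setdiff(unique(default_name_map()$commercial_name),
    names(FOCAL_NAME_COUNTS)
  )
  stopifnot(length(rare_names) == 30L)
  rare_counts <- setNames(
    c(5L, 5L, 4L, 4L, 3L, 3L, 3L, 3L, rep(2L, 8L), rep(1L, 14L)),
    rare_names
  )
  name_counts <- c(FOCAL_NAME_COUNTS, rare_counts, pescado = 7L)
  mislabel_prob <- c(
    FOCAL_NAME_MISLABEL_COUNTS / FOCAL_NAME_COUNTS,
    setNames(rep(17 / 60, length(rare_names)), rare_names),
    pescado = 0
  )
  survey_design(
    name_counts = name_counts,
    mislabel_prob = mislabel_prob,
    cities = c("Mazatlan", "Mexico City", "Cancun"),
    city_weights = c(120, 150, 106),
    vendor_weights = c(107, 78, 191),
    source_weights = c(label = 0.22, menu = 0.33, verbal = 0.45),
    generic_names = "pescado",
    intra_divergence = 0.01,
    substitution_gamma = 0.8
  )
}
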