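# Static ISO 3166-1 alpha-2 -> continent mapping used for the "Area" rows of
# the demographics table. Unmapped or empty codes report as "Unknown".

iso2_continent <- local({
  m <- c(
    # Africa
    DZ = "Africa", AO = "Africa", BJ = "Africa", BW = "Africa", BF = "Africa",
    BI = "Africa", CM = "Africa", CV = "Africa", CF = "Africa", TD = "Africa",
    KM = "Africa", CG = "Africa", CD = "Africa", CI = "Africa", DJ = "Africa",
    EG = "Africa", GQ = "Africa", ER = "Africa", SZ = "Africa", ET = "Africa",
    GA = "Africa", GM = "Africa", GH = "Africa", GN = "Africa", GW = "Africa",
    KE = "Africa", LS = "Africa", LR = "Africa", LY = "Africa", MG = "Africa",
    MW = "Africa", ML = "Africa", MR = "Africa", MU = "Africa", MA = "Africa",
    MZ = "Africa", NA_ = "Africa", NE = "Africa", NG = "Africa", RW = "Africa",
    ST = "Africa", SN = "Africa", SC = "Africa", SL = "Africa", SO = "Africa",
    ZA = "Africa", SS = "Africa", SD = "Africa", TZ = "Africa", TG = "Africa",
    TN = "Africa", UG = "Africa", ZM = "Africa", ZW = "Africa", RE = "Africa",
    # Asia
    AF = "Asia", AM = "Asia", AZ = "Asia", BH = "Asia", BD = "Asia",
    BT = "Asia", BN = "Asia", KH = "Asia", CN = "Asia", CY = "Asia",
    GE = "Asia", HK = "Asia", IN = "Asia", ID = "Asia", IR = "Asia",
    IQ = "Asia", IL = "Asia", JP = "Asia", JO = "Asia", KZ = "Asia",
    KW = "Asia", KG = "Asia", LA = "Asia", LB = "Asia", MO = "Asia",
    MY = "Asia", MV = "Asia", MN = "Asia", MM = "Asia", NP = "Asia",
    KP = "Asia", OM = "Asia", PK = "Asia", PS = "Asia", PH = "Asia",
    QA = "Asia", SA = "Asia", SG = "Asia", KR = "Asia", LK = "Asia",
    SY = "Asia", TW = "Asia", TJ = "Asia", TH = "Asia", TL = "Asia",
    TR = "Asia", TM = "Asia", AE = "Asia", UZ = "Asia", VN = "Asia",
    YE = "Asia",
    # Europe
    AL = "Europe", AD = "Europe", AT = "Europe", BY = "Europe", BE = "Europe",
    BA = "Europe", BG = "Europe", HR = "Europe", CZ = "Europe", DK = "Europe",
    EE = "Europe", FI = "Europe", FR = "Europe", DE = "Europe", GR = "Europe",
    HU = "Europe", IS = "Europe", IE = "Europe", IT = "Europe", XK = "Europe",
    LV = "Europe", LI = "Europe", LT = "Europe", LU = "Europe", MT = "Europe",
    MD = "Europe", MC = "Europe", ME = "Europe", NL = "Europe", MK = "Europe",
    NO = "Europe", PL = "Europe", PT = "Europe", RO = "Europe", RU = "Europe",
    SM = "Europe", RS = "Europe", SK = "Europe", SI = "Europe", ES = "Europe",
    SE = "Europe", CH = "Europe", UA = "Europe", GB = "Europe", VA = "Europe",
    GI = "Europe", GG = "Europe", JE = "Europe", IM = "Europe", FO = "Europe",
    # Oceania
    AU = "Oceania", FJ = "Oceania", KI = "Oceania", MH = "Oceania",
    FM = "Oceania", NR = "Oceania", NZ = "Oceania", PW = "Oceania",
    PG = "Oceania", WS = "Oceania", SB = "Oceania", TO = "Oceania",
    TV = "Oceania", VU = "Oceania", NC = "Oceania", PF = "Oceania",
    GU = "Oceania",
    # North America (incl. Central America and the Caribbean)
    AG = "North America", BS = "North America", BB = "North America",
    BZ = "North America", CA = "North America", CR = "North America",
    CU = "North America", DM = "North America", DO = "North America",
    SV = "North America", GD = "North America", GT = "North America",
    HT = "North America", HN = "North America", JM = "North America",
    MX = "North America", NI = "North America", PA = "North America",
    KN = "North America", LC = "North America", VC = "North America",
    TT = "North America", US = "North America", PR = "North America",
    BM = "North America", GL = "North America", KY = "North America",
    # South America
    AR = "South America", BO = "South America", BR = "South America",
    CL = "South America", CO = "South America", EC = "South America",
    GY = "South America", PY = "South America", PE = "South America",
    SR = "South America", UY = "South America", VE = "South America",
    GF = "South America")
  names(m)[names(m) == "NA_"] <- "NA"  # Namibia
  m
})

#' Map ISO country codes to continents
#' @param country character vector of ISO 3166-1 alpha-2 codes.
#' @return character vector of continents, \code{"Unknown"} when unmapped.
#' @export
country_to_region <- function(country) {
  out <- iso2_continent[toupper(trimws(country))]
  out[is.na(out)] <- "Unknown"
  unname(out)
}
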