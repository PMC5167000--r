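#' Destrieux sulco-gyral region labels
#'
#' The cortical parcel labels of the Destrieux atlas as used by FreeSurfer
#' (`aparc.a2009s`): 74 sulco-gyral parcels per hemisphere. Study reports
#' sometimes quote 75 regions per hemisphere; that count includes the
#' non-cortical medial-wall label, which carries no meaningful thickness and
#' is therefore not part of the default list here. All package functions
#' accept arbitrary region name sets, so analyses are not tied to this list.
#'
#' @return Character vector of 74 region names.
#' @examples
#' length(destrieux_labels())
#' grep("insula", destrieux_labels(), value = TRUE)
#' @export
destrieux_labels <- function() {
  c(
    "G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
    "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
    "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
    "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
    "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
    "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
    "G_insular_short", "G_occipital_middle", "G_occipital_sup",
    "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip",
    "G_orbital", "G_pariet_inf-Angular", "G_pariet_inf-Supramar",
    "G_parietal_sup", "G_postcentral", "G_precentral", "G_precuneus",
    "G_rectus", "G_subcallosal", "G_temp_sup-G_T_transv",
    "G_temp_sup-Lateral", "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo",
    "G_temporal_inf", "G_temporal_middle", "Lat_Fis-ant-Horizont",
    "Lat_Fis-ant-Vertical", "Lat_Fis-post", "Pole_occipital",
    "Pole_temporal", "S_calcarine", "S_central", "S_cingul-Marginalis",
    "S_circular_insula_ant", "S_circular_insula_inf",
    "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
    "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
    "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
    "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
    "S_oc-temp_med_and_Lingual", "S_orbital_lateral", "S_orbital_med-olfact",
    "S_orbital-H_Shaped", "S_parieto_occipital", "S_pericallosal",
    "S_postcentral", "S_precentral-inf-part", "S_precentral-sup-part",
    "S_suborbital", "S_subparietal", "S_temporal_inf", "S_temporal_sup",
    "S_temporal_transverse"
  )
}

hemi_prefix <- c(left = "lh", right = "rh")

#' Build and parse `aparcstats2table`-style thickness column names
#'
#' Regional thickness columns follow the FreeSurfer `aparcstats2table`
#' dialect `<hemi>_<region>_thickness` with `hemi` one of `lh`/`rh`, e.g.
#' `lh_S_circular_insula_ant_thickness`.
#'
#' @param hemisphere Character vector, `"left"` or `"right"` (recycled).
#' @param region Character vector of Destrieux region names.
#' @return `thickness_key()`: character vector of column names.
#' @examples
#' thickness_key("left", "S_circular_insula_ant")
#' parse_thickness_key("lh_S_circular_insula_ant_thickness")
#' @export
thickness_key <- function(hemisphere, region) {
  hemisphere <- match.arg(hemisphere, c("left", "right"), several.ok = TRUE)
  paste0(hemi_prefix[hemisphere], "_", region, "_thickness")
}

#' @rdname thickness_key
#' @param key Character vector of column names to parse.
#' @return `parse_thickness_key()`: data.frame with columns `key`,
#'   `hemisphere` (`left`/`right`) and `region`.
#' @export
parse_thickness_key <- function(key) {
  m <- regmatches(key, regexec("^(lh|rh)_(.+)_thickness$", key))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("thickness column name(s) not in '<lh|rh>_<region>_thickness' form: ",
         paste(key[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    key = key,
    hemisphere = c(lh = "left", rh = "right")[vapply(m, `[`, "", 2L)],
    region = vapply(m, `[`, "", 3L),
    row.names = NULL
  )
}
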