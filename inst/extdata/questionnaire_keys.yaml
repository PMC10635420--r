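# Item-to-subscale keys for the self-report instruments used in the
# validation analyses. Item counts follow the published instruments:
# ETSRS (Heat-Induced Warming 5, Heat Perception 7), STRAQ-1 (High
# Temperature Sensitivity 7, Solitary Thermoregulation 8, Social
# Thermoregulation 5), MAIA-2 (37 items over 8 subscales), BPQ-SF (22 items
# scored as a single body-awareness scale). Item identifiers are synthetic
# placeholders: real studies should replace them with their own item ids and
# mark reverse-coded items in `reverse`.
etsrs:
  range: [1, 7]
  reverse: []
  subscales:
    heat_induced_warming: [etsrs_hiw_1, etsrs_hiw_2, etsrs_hiw_3, etsrs_hiw_4, etsrs_hiw_5]
    heat_perception: [etsrs_hp_1, etsrs_hp_2, etsrs_hp_3, etsrs_hp_4, etsrs_hp_5, etsrs_hp_6, etsrs_hp_7]
straq1:
  range: [1, 5]
  reverse: []
  subscales:
    high_temp_sensitivity: [straq1_hts_1, straq1_hts_2, straq1_hts_3, straq1_hts_4, straq1_hts_5, straq1_hts_6, straq1_hts_7]
    solitary_thermoregulation: [straq1_sot_1, straq1_sot_2, straq1_sot_3, straq1_sot_4, straq1_sot_5, straq1_sot_6, straq1_sot_7, straq1_sot_8]
    social_thermoregulation: [straq1_sct_1, straq1_sct_2, straq1_sct_3, straq1_sct_4, straq1_sct_5]
maia2:
  range: [0, 5]
  reverse: []
  subscales:
    noticing: [maia2_not_1, maia2_not_2, maia2_not_3, maia2_not_4]
    not_distracting: [maia2_nd_1, maia2_nd_2, maia2_nd_3, maia2_nd_4, maia2_nd_5, maia2_nd_6]
    not_worrying: [maia2_nw_1, maia2_nw_2, maia2_nw_3, maia2_nw_4, maia2_nw_5]
    attention_regulation: [maia2_ar_1, maia2_ar_2, maia2_ar_3, maia2_ar_4, maia2_ar_5, maia2_ar_6, maia2_ar_7]
    emotional_awareness: [maia2_ea_1, maia2_ea_2, maia2_ea_3, maia2_ea_4, maia2_ea_5]
    self_regulation: [maia2_sr_1, maia2_sr_2, maia2_sr_3, maia2_sr_4]
    body_listening: [maia2_bl_1, maia2_bl_2, maia2_bl_3]
    trusting: [maia2_tr_1, maia2_tr_2, maia2_tr_3]
bpq_sf:
  range: [1, 5]
  reverse: []
  subscales:
    body_awareness: [bpq_1, bpq_2, bpq_3, bpq_4, bpq_5, bpq_6, bpq_7, bpq_8, bpq_9, bpq_10, bpq_11, bpq_12, bpq_13, bpq_14, bpq_15, bpq_16, bpq_17, bpq_18, bpq_19, bpq_20, bpq_21, bpq_22]
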