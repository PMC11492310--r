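# Canonical structure registry for the head-and-neck CTV pipeline.
# Laterality is carried as a "_L"/"_R" suffix on the canonical name;
# common laterality spellings are listed under lateral_aliases and are
# matched as prefixes or suffixes case-insensitively.
structures:
  - name: brain
  - name: brainstem
    aliases: [brain_stem]
  - name: clivus
  - name: skull_base
    aliases: [skullbase]
  - name: c1_vertebral_body
    aliases: [c1, vertebral_body_c1]
  - name: c2_vertebral_body
    aliases: [c2, vertebral_body_c2]
  - name: spinal_cord
    aliases: [cord, spinalcord]
  - name: orbit_L
  - name: orbit_R
    aliases: [eye]
  - name: optic_nerve_L
  - name: optic_nerve_R
    aliases: [opticnerve]
  - name: optic_chiasm
    aliases: [chiasm]
  - name: nasopharynx
    aliases: [np]
  - name: maxillary_sinus_L
  - name: maxillary_sinus_R
    aliases: [maxillary]
  - name: sphenoid_sinus
    aliases: [sphenoid]
  - name: nasal_cavity
  - name: hyoid
    aliases: [hyoid_bone]
  - name: cricoid
    aliases: [cricoid_cartilage]
  - name: mastoid_L
  - name: mastoid_R
  - name: pterygoid_fossa_L
  - name: pterygoid_fossa_R
    aliases: [pterygoid]
  - name: parotid_L
  - name: parotid_R
    aliases: [parotid_gland]
  - name: larynx
  - name: mandible
  - name: vertebral_column
    aliases: [spine]
  - name: LN_Ib_L
  - name: LN_Ib_R
    aliases: [lymph_node_ib, level_ib, ln_1b]
  - name: LN_II_L
  - name: LN_II_R
    aliases: [lymph_node_ii, level_ii, ln_2]
  - name: LN_III_L
  - name: LN_III_R
    aliases: [lymph_node_iii, level_iii, ln_3]
  - name: LN_IV_L
  - name: LN_IV_R
    aliases: [lymph_node_iv, level_iv, ln_4]
  - name: LN_Va_L
  - name: LN_Va_R
    aliases: [lymph_node_va, level_va]
  - name: LN_Vb_L
  - name: LN_Vb_R
    aliases: [lymph_node_vb, level_vb]
  - name: LN_RP_L
  - name: LN_RP_R
    aliases: [lymph_node_rp, retropharyngeal, rp_node]
lateral_aliases:
  L: [l, left, lt, lft]
  R: [r, right, rt, rgt]
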