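# Landmark rule table for the intermediate-dose primary target (CTV3p).
#
# Rules are data, not code, so the engine can be re-pointed at another
# contouring guideline by overriding this file (ctvConfig(landmark_rules=)).
#
# Anchor coordinates are fractions of the structure's per-slice bounding
# box: fx runs 0 -> 1 with increasing x (patient right -> left), fy runs
# 0 -> 1 from the anterior edge to the posterior edge. Anchors are
# snapped to the nearest point of the 7 x 7 candidate grid spanning the
# box (ties toward the smaller coordinate).
#
# condition: none | clivus_invaded | clivus_not_invaded
# lateral_shift_if_involved: on the hemineck holding (or shared by) the
#   primary GTV the anchor's fx moves to the lateral box edge.
rules:
  - structure: maxillary_sinus_L
    groups: [5, 6, 7]
    anchors: [{fx: 0.0, fy: 0.75}, {fx: 1.0, fy: 0.75}]
  - structure: maxillary_sinus_R
    groups: [5, 6, 7]
    anchors: [{fx: 0.0, fy: 0.75}, {fx: 1.0, fy: 0.75}]
  - structure: clivus
    groups: [4, 5, 6]
    condition: clivus_not_invaded
    anchors: [{fx: 0.0, fy: 0.3333333}, {fx: 1.0, fy: 0.3333333}]
  - structure: clivus
    groups: [4, 5, 6]
    condition: clivus_invaded
    anchors: [{fx: 0.0, fy: 1.0}, {fx: 1.0, fy: 1.0}]
  - structure: LN_RP_L
    groups: [1, 2, 3]
    anchors: [{fx: 0.5, fy: 0.0}]
  - structure: LN_RP_R
    groups: [1, 2, 3]
    anchors: [{fx: 0.5, fy: 0.0}]
  - structure: pterygoid_fossa_L
    groups: [1, 2, 3, 4, 5]
    anchors: [{fx: 0.5, fy: 0.0}]
    lateral_shift_if_involved: true
  - structure: pterygoid_fossa_R
    groups: [1, 2, 3, 4, 5]
    anchors: [{fx: 0.5, fy: 0.0}]
    lateral_shift_if_involved: true
  - structure: nasopharynx
    groups: [2, 3, 4, 5]
    anchors: [{fx: 0.0, fy: 0.0}, {fx: 1.0, fy: 0.0},
              {fx: 0.0, fy: 1.0}, {fx: 1.0, fy: 1.0}]
  - structure: mastoid_L
    groups: [2]
    anchors: [{fx: 1.0, fy: 0.0}, {fx: 1.0, fy: 1.0}]
  - structure: mastoid_R
    groups: [2]
    anchors: [{fx: 0.0, fy: 0.0}, {fx: 0.0, fy: 1.0}]
  - structure: sphenoid_sinus
    groups: [6, 7, 8]
    anchors: [{fx: 0.0, fy: 0.0}, {fx: 1.0, fy: 0.0},
              {fx: 0.0, fy: 1.0}, {fx: 1.0, fy: 1.0}]
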