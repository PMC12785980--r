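# Default rulebase and radiological ontology for the fuzzy reasoning layer.
#
# The effusion and pneumothorax clauses follow the two explicitly published
# rule forms; the cardiomegaly clause encodes the cardiothoracic-ratio
# heuristic; the remaining eleven clauses are templated reconstructions, one
# per class, bound to the class's primary anatomical region. Reference
# levels (tau_ref), rule thresholds, weights and the penalty are editable
# configuration, chosen once as symmetric defaults: confidence threshold 0.5,
# spatial-support threshold 0.05, activation reference level 0.4,
# cardiothoracic reference 0.5 (the conventional ratio cutoff).

fuzzy:
  beta: 10.0
  beta_classifier: 2.0   # acts on log(p_c / tau_c)
ranking:
  alpha: 5.0
conflict_penalty: 0.5
weights:
  anatomical: 1.0
  classifier: 1.0

ontology:
  root: Thoracic Finding
  is_a:
    - [Effusion, Fluid Collection Abnormality]
    - [Edema, Fluid Collection Abnormality]
    - [Cardiomegaly, Cardiac Size Abnormality]
    - [Pneumothorax, Air Collection Abnormality]
    - [Emphysema, Air Collection Abnormality]
    - [Atelectasis, Parenchymal Abnormality]
    - [Consolidation, Parenchymal Abnormality]
    - [Infiltration, Parenchymal Abnormality]
    - [Pneumonia, Parenchymal Abnormality]
    - [Fibrosis, Parenchymal Abnormality]
    - [Mass, Focal Lesion]
    - [Nodule, Focal Lesion]
    - [Pleural Thickening, Pleural Abnormality]
    - [Hernia, Diaphragmatic Abnormality]
    - [Fluid Collection Abnormality, Thoracic Finding]
    - [Cardiac Size Abnormality, Thoracic Finding]
    - [Air Collection Abnormality, Thoracic Finding]
    - [Parenchymal Abnormality, Thoracic Finding]
    - [Focal Lesion, Thoracic Finding]
    - [Pleural Abnormality, Thoracic Finding]
    - [Diaphragmatic Abnormality, Thoracic Finding]

predicates:
  - name: Atelectasis
    region: mid_lung
    conf_cue: activation_atelectasis
    tau_ref: 0.4
    template: "{strength} focal activity along the {region} and cardiac border with volume-loss pattern, compatible with atelectasis."
  - name: Cardiomegaly
    region: heart
    conf_cue: cardiothoracic_ratio
    tau_ref: 0.5
    template: "Generalised increased activity through the cardiac silhouette with a raised cardiothoracic ratio ({strength}), compatible with cardiomegaly."
  - name: Consolidation
    region: mid_lung
    conf_cue: activation_consolidation
    tau_ref: 0.4
    template: "{strength} dense opacification of the affected lobar segments in the {region}, compatible with consolidation."
  - name: Edema
    region: basal_lung
    conf_cue: activation_edema
    tau_ref: 0.4
    template: "{strength} perihilar and basal activity in the {region}, compatible with pulmonary edema."
  - name: Effusion
    region: costophrenic
    conf_cue: basal_activation
    tau_ref: 0.4
    template: "High activity noted in the lower lung base with blunting of the costophrenic angle ({strength}), which is compatible with pleural effusion."
  - name: Emphysema
    region: lung
    conf_cue: activation_emphysema
    tau_ref: 0.4
    template: "{strength} hyperlucency across the {region} fields with diaphragmatic flattening, compatible with emphysema."
  - name: Fibrosis
    region: basal_lung
    conf_cue: activation_fibrosis
    tau_ref: 0.4
    template: "{strength} interstitial banding in the {region} zones, compatible with fibrosis."
  - name: Hernia
    region: basal_lung
    conf_cue: activation_hernia
    tau_ref: 0.4
    template: "{strength} focal activity at the diaphragmatic dome in the {region}, compatible with hernia."
  - name: Infiltration
    region: lung
    conf_cue: activation_infiltration
    tau_ref: 0.4
    template: "{strength} diffuse heterogeneous activity across the parenchymal {region} fields, compatible with infiltration."
  - name: Mass
    region: lung
    conf_cue: activation_mass
    tau_ref: 0.4
    template: "{strength} focal nodular opacity within the pulmonary {region} field, compatible with a mass."
  - name: Nodule
    region: lung
    conf_cue: activation_nodule
    tau_ref: 0.4
    template: "{strength} discrete small pulmonary lesion in the {region} field, compatible with a nodule."
  - name: Pneumonia
    region: mid_lung
    conf_cue: activation_pneumonia
    tau_ref: 0.4
    template: "{strength} patchy parenchymal activity in the {region}, compatible with pneumonia."
  - name: Pleural Thickening
    region: lateral_lung
    conf_cue: activation_pleural_thickening
    tau_ref: 0.4
    template: "{strength} activity along the pleural margin of the {region} wall, compatible with pleural thickening."
  - name: Pneumothorax
    region: apical_lung
    conf_cue: apical_gradient
    tau_ref: 0.4
    template: "{strength} apical lucency with a sharp pleural edge in the {region}, compatible with pneumothorax."

conflicts:
  - a: Pneumothorax
    b: Effusion
    qualifier: same_side

rules:
  - id: effusion_costophrenic
    antecedents:
      - {cue: mu_effusion, op: ">", threshold: 0.5}
      - {cue: activation_effusion, op: ">", threshold: 0.05}
      - {cue: basal_image_density, op: ">", threshold: 0.35}
    consequent: Effusion
    confidence: mu_effusion
  - id: pneumothorax_apical
    antecedents:
      - {cue: mu_pneumothorax, op: ">", threshold: 0.5}
      - {cue: activation_pneumothorax, op: ">", threshold: 0.05}
    consequent: Pneumothorax
    confidence: mu_pneumothorax
  - id: cardiomegaly_ratio
    antecedents:
      - {cue: mu_cardiomegaly, op: ">", threshold: 0.5}
      - {cue: cardiothoracic_ratio, op: ">", threshold: 0.5}
    consequent: Cardiomegaly
    confidence: mu_cardiomegaly
  - id: atelectasis_region
    antecedents:
      - {cue: mu_atelectasis, op: ">", threshold: 0.5}
      - {cue: activation_atelectasis, op: ">", threshold: 0.05}
    consequent: Atelectasis
    confidence: mu_atelectasis
  - id: consolidation_region
    antecedents:
      - {cue: mu_consolidation, op: ">", threshold: 0.5}
      - {cue: activation_consolidation, op: ">", threshold: 0.05}
    consequent: Consolidation
    confidence: mu_consolidation
  - id: edema_region
    antecedents:
      - {cue: mu_edema, op: ">", threshold: 0.5}
      - {cue: activation_edema, op: ">", threshold: 0.05}
    consequent: Edema
    confidence: mu_edema
  - id: emphysema_region
    antecedents:
      - {cue: mu_emphysema, op: ">", threshold: 0.5}
      - {cue: activation_emphysema, op: ">", threshold: 0.05}
    consequent: Emphysema
    confidence: mu_emphysema
  - id: fibrosis_region
    antecedents:
      - {cue: mu_fibrosis, op: ">", threshold: 0.5}
      - {cue: activation_fibrosis, op: ">", threshold: 0.05}
    consequent: Fibrosis
    confidence: mu_fibrosis
  - id: hernia_region
    antecedents:
      - {cue: mu_hernia, op: ">", threshold: 0.5}
      - {cue: activation_hernia, op: ">", threshold: 0.05}
    consequent: Hernia
    confidence: mu_hernia
  - id: infiltration_region
    antecedents:
      - {cue: mu_infiltration, op: ">", threshold: 0.5}
      - {cue: activation_infiltration, op: ">", threshold: 0.05}
    consequent: Infiltration
    confidence: mu_infiltration
  - id: mass_region
    antecedents:
      - {cue: mu_mass, op: ">", threshold: 0.5}
      - {cue: activation_mass, op: ">", threshold: 0.05}
    consequent: Mass
    confidence: mu_mass
  - id: nodule_region
    antecedents:
      - {cue: mu_nodule, op: ">", threshold: 0.5}
      - {cue: activation_nodule, op: ">", threshold: 0.05}
    consequent: Nodule
    confidence: mu_nodule
  - id: pneumonia_region
    antecedents:
      - {cue: mu_pneumonia, op: ">", threshold: 0.5}
      - {cue: activation_pneumonia, op: ">", threshold: 0.05}
    consequent: Pneumonia
    confidence: mu_pneumonia
  - id: pleural_thickening_region
    antecedents:
      - {cue: mu_pleural_thickening, op: ">", threshold: 0.5}
      - {cue: activation_pleural_thickening, op: ">", threshold: 0.05}
    consequent: Pleural Thickening
    confidence: mu_pleural_thickening
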