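# Laparoscopic Roux-en-Y gastric bypass (LRYGB) annotation ontology.
# 12 phases / 46 steps, hierarchically structured; facultative elements may
# legitimately be absent from an individual procedure. Step wording is a
# synthetic transcription assembled from standard LRYGB operative technique;
# all package computations depend on label identity only, never on name text.
name: lrygb
version: "1.0"
idle_label: idle
phases:
  - {id: 1, name: "Preparation and abdominal access", facultative: true}
  - {id: 2, name: "Gastric pouch creation", facultative: false}
  - {id: 3, name: "Omentum division", facultative: true}
  - {id: 4, name: "Gastrojejunal anastomosis", facultative: false}
  - {id: 5, name: "Anastomotic test", facultative: true}
  - {id: 6, name: "Jejunal separation", facultative: false}
  - {id: 7, name: "Petersen space closure", facultative: true}
  - {id: 8, name: "Jejunojejunal anastomosis", facultative: false}
  - {id: 9, name: "Mesenteric defect closure", facultative: true}
  - {id: 10, name: "Cleaning and coagulation", facultative: true}
  - {id: 11, name: "Disassembling and closure", facultative: false}
  - {id: 12, name: "Other intervention", facultative: true}
steps:
  - {id: 1, name: "Trocar placement", facultative: false, parent_phase_id: 1}
  - {id: 2, name: "Abdominal cavity exploration", facultative: false, parent_phase_id: 1}
  - {id: 3, name: "Access adhesiolysis", facultative: true, parent_phase_id: 1}
  - {id: 4, name: "Liver retractor placement", facultative: true, parent_phase_id: 1}
  - {id: 5, name: "Angle of His dissection", facultative: false, parent_phase_id: 2}
  - {id: 6, name: "Lesser curvature dissection", facultative: false, parent_phase_id: 2}
  - {id: 7, name: "Retrogastric tunnel creation", facultative: false, parent_phase_id: 2}
  - {id: 8, name: "Horizontal gastric stapling", facultative: false, parent_phase_id: 2}
  - {id: 9, name: "Vertical gastric stapling", facultative: false, parent_phase_id: 2}
  - {id: 10, name: "Pouch calibration", facultative: true, parent_phase_id: 2}
  - {id: 11, name: "Pouch haemostasis", facultative: true, parent_phase_id: 2}
  - {id: 12, name: "Omentum grasping", facultative: false, parent_phase_id: 3}
  - {id: 13, name: "Omentum transection", facultative: false, parent_phase_id: 3}
  - {id: 14, name: "Jejunal loop measurement", facultative: false, parent_phase_id: 4}
  - {id: 15, name: "Gastrotomy", facultative: false, parent_phase_id: 4}
  - {id: 16, name: "Jejunal enterotomy", facultative: false, parent_phase_id: 4}
  - {id: 17, name: "Stapled gastrojejunostomy", facultative: false, parent_phase_id: 4}
  - {id: 18, name: "Gastrojejunostomy defect closure", facultative: false, parent_phase_id: 4}
  - {id: 19, name: "Gastrojejunostomy reinforcement", facultative: true, parent_phase_id: 4}
  - {id: 20, name: "Gastrojejunostomy haemostasis", facultative: true, parent_phase_id: 4}
  - {id: 21, name: "Methylene blue test", facultative: false, parent_phase_id: 5}
  - {id: 22, name: "Air leak test", facultative: true, parent_phase_id: 5}
  - {id: 23, name: "Mesentery exposure", facultative: false, parent_phase_id: 6}
  - {id: 24, name: "Mesentery division", facultative: true, parent_phase_id: 6}
  - {id: 25, name: "Jejunal stapling", facultative: false, parent_phase_id: 6}
  - {id: 26, name: "Separation verification", facultative: false, parent_phase_id: 6}
  - {id: 27, name: "Petersen space exposure", facultative: false, parent_phase_id: 7}
  - {id: 28, name: "Petersen space suturing", facultative: false, parent_phase_id: 7}
  - {id: 29, name: "Biliary limb measurement", facultative: false, parent_phase_id: 8}
  - {id: 30, name: "Limb approximation", facultative: false, parent_phase_id: 8}
  - {id: 31, name: "Jejunojejunostomy enterotomies", facultative: false, parent_phase_id: 8}
  - {id: 32, name: "Stapled jejunojejunostomy", facultative: false, parent_phase_id: 8}
  - {id: 33, name: "Jejunojejunostomy defect closure", facultative: false, parent_phase_id: 8}
  - {id: 34, name: "Jejunojejunostomy reinforcement", facultative: true, parent_phase_id: 8}
  - {id: 35, name: "Jejunojejunostomy haemostasis", facultative: true, parent_phase_id: 8}
  - {id: 36, name: "Mesenteric defect exposure", facultative: false, parent_phase_id: 9}
  - {id: 37, name: "Mesenteric defect suturing", facultative: false, parent_phase_id: 9}
  - {id: 38, name: "Irrigation and suction", facultative: false, parent_phase_id: 10}
  - {id: 39, name: "Targeted coagulation", facultative: true, parent_phase_id: 10}
  - {id: 40, name: "Instrument and retractor removal", facultative: false, parent_phase_id: 11}
  - {id: 41, name: "Trocar removal and port closure", facultative: false, parent_phase_id: 11}
  - {id: 42, name: "Concomitant cholecystectomy", facultative: true, parent_phase_id: 12}
  - {id: 43, name: "Hiatal hernia repair", facultative: true, parent_phase_id: 12}
  - {id: 44, name: "Extensive adhesiolysis", facultative: true, parent_phase_id: 12}
  - {id: 45, name: "Tissue biopsy", facultative: true, parent_phase_id: 12}
  - {id: 46, name: "Unclassified action", facultative: true, parent_phase_id: 12}
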