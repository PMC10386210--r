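name: glaucoma_smq_narrow
provenance: >-
  Narrow-scope standardized MedDRA query for glaucoma (MedDRA/J version 25.0);
  the 32 preferred terms remaining after exclusion of congenital, traumatic,
  postoperative, and surgical terms. Two typographically corrupted spellings
  seen in circulation are carried as synonyms of the cleaned terms.
pts:
  - Acute myopia
  - Angle-closure glaucoma
  - Aphakic glaucoma
  - Borderline glaucoma
  - Diabetic glaucoma
  - Exfoliation glaucoma
  - Fundoscopy abnormal
  - Glaucoma
  - Glaucoma drug therapy
  - Glaucomatocyclitic crises
  - Glaucomatous optic disc atrophy
  - Gonioscopy abnormal
  - Halo vision
  - Intraocular pressure fluctuation
  - Intraocular pressure increased
  - Intraocular pressure test abnormal
  - Loss of visual contrast sensitivity
  - Malignant glaucoma
  - Normal tension glaucoma
  - Ocular hypertension
  - Open-angle glaucoma
  - Optic discs blurred
  - Optic nerve cup/disc ratio increased
  - Optic nerve cupping
  - Phacolytic glaucoma
  - Pigmentary glaucoma
  - Pseudophakic glaucoma
  - Pupillary light reflex tests abnormal
  - Slit-lamp tests abnormal
  - Uveitic glaucoma
  - Uveitis-glaucoma-hyphaema syndrome
  - Visual field tests abnormal
synonyms:
  "The optical nerve cup/disc ratio increased": "Optic nerve cup/disc ratio increased"
  "The visualVisual field tests abnormal": "Visual field tests abnormal"
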