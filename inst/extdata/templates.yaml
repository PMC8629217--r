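# Sentence template banks for the synthetic chest X-ray report generator.
# Reports cover four anatomical topics in a fixed order behind a shared
# opening sentence; normal sentences are heavily reused across reports and
# phrase negated findings with the cues the bundled lexicon recognizes.
# Every sentence is pre-tokenized lowercase alphabetic text.
opening:
  - frontal and lateral views of the chest were obtained
  - two views of the chest were obtained
  - pa and lateral chest views are available for review
topic_order: [heart, lungs, pleura, bones]
topics:
  heart:
    categories: [cardiomegaly]
    normal:
      - the heart is normal in size
      - heart size within normal limits
      - the cardiac silhouette and mediastinal contours are within normal limits
      - there is no cardiomegaly identified
    abnormal:
      cardiomegaly:
        - the heart is enlarged with moderate cardiomegaly
        - stable moderate cardiomegaly is again seen
        - mild cardiomegaly is present
  lungs:
    categories: [consolidation, pneumothorax, atelectasis]
    normal:
      - the lungs are clear without focal consolidation
      - lungs are clear and no pneumothorax is seen
      - the lungs are well expanded and clear
      - no focal consolidation is seen
    abnormal:
      consolidation:
        - there is focal consolidation in the right lower lobe
        - patchy consolidation is present at the left base
      pneumothorax:
        - a small apical pneumothorax is present
        - there is a moderate right pneumothorax
      atelectasis:
        - bibasilar atelectasis is noted
        - streaky atelectasis is present at the bases
  pleura:
    categories: [pleural_effusion, edema]
    normal:
      - no pleural effusion is seen
      - there is no pulmonary edema
      - no effusion and no edema is identified
    abnormal:
      pleural_effusion:
        - a small left pleural effusion is present
        - there is a layering right pleural effusion
      edema:
        - there is mild interstitial pulmonary edema
        - pulmonary edema is present
  bones:
    categories: [fracture]
    normal:
      - the bony structures are intact
      - no acute fracture is identified
      - the visualized osseous structures are unremarkable
    abnormal:
      fracture:
        - there is an acute fracture of a left rib
        - a displaced rib fracture is noted
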