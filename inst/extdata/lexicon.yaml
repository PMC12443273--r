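# Starter NCD lexicon: category -> list of {label, en: [...], th: [...]}.
# English terms are matched as contiguous token subsequences after
# normalization; Thai terms are matched as substrings of the raw text.
# The four disease groups cover the classic NCD categories (cancer,
# cardiovascular disease, diabetes, chronic respiratory disease).
disease:
  - label: cancer
    en: [cancer, tumor, tumour, carcinoma, leukemia, lymphoma]
    th: [มะเร็ง, เนื้องอก]
  - label: heart_disease
    en: [heart disease, heart attack, cardiovascular disease, coronary, heart failure, stroke]
    th: [โรคหัวใจ, หัวใจวาย, หลอดเลือดหัวใจ]
  - label: diabetes
    en: [diabetes, diabetic, blood sugar disease]
    th: [เบาหวาน]
  - label: chronic_respiratory_disease
    en: [copd, emphysema, asthma, chronic bronchitis, lung disease]
    th: [ถุงลมโป่งพอง, หอบหืด, โรคปอด]
  - label: hypertension
    en: [hypertension, high blood pressure]
    th: [ความดันโลหิตสูง, ความดันสูง]
symptom:
  - label: fatigue
    en: [fatigue, tired, exhausted, weakness]
    th: [เหนื่อย, อ่อนเพลีย, เหนื่อยง่าย]
  - label: chest_pain
    en: [chest pain, chest tightness]
    th: [เจ็บหน้าอก, แน่นหน้าอก]
  - label: cough
    en: [cough, coughing]
    th: [ไอเรื้อรัง, อาการไอ]
  - label: shortness_of_breath
    en: [shortness of breath, breathless, wheezing]
    th: [หอบ, หายใจลำบาก]
  - label: high_blood_sugar
    en: [high blood sugar, hyperglycemia]
    th: [น้ำตาลสูง, น้ำตาลขึ้น]
  - label: numbness
    en: [numbness, numb, tingling]
    th: [ชาปลายมือ, ชาปลายเท้า, มือชา, เท้าชา]
  - label: slow_healing_wound
    en: [slow healing, wound not healing]
    th: [แผลหายช้า]
  - label: headache
    en: [headache, dizziness, dizzy]
    th: [ปวดหัว, เวียนหัว]
treatment:
  - label: chemotherapy
    en: [chemotherapy, chemo]
    th: [คีโม, เคมีบำบัด]
  - label: radiotherapy
    en: [radiation, radiotherapy]
    th: [ฉายแสง, รังสีรักษา]
  - label: surgery
    en: [surgery, operation, operated]
    th: [ผ่าตัด]
  - label: insulin
    en: [insulin]
    th: [อินซูลิน, ฉีดอินซูลิน]
  - label: medication
    en: [medication, medicine, pills, drug]
    th: [กินยา, ทานยา, ยารักษา]
  - label: dialysis
    en: [dialysis]
    th: [ฟอกไต]
behavior_cause:
  - label: smoking
    en: [smoking, smoker, cigarette, cigarettes]
    th: [สูบบุหรี่, บุหรี่]
  - label: alcohol
    en: [alcohol, drinking, drinker]
    th: [ดื่มเหล้า, เหล้า, แอลกอฮอล์]
  - label: diet
    en: [sugary food, sweet food, junk food, fatty food]
    th: [อาหารหวาน, กินหวาน, ของทอด]
  - label: exercise
    en: [exercise, workout, jogging]
    th: [ออกกำลังกาย]
  - label: air_pollution
    en: [air pollution, pm2.5, smog]
    th: [ฝุ่น, มลพิษ]
gender_cue:
  - label: male
    en: [mr, sir, husband, grandfather, "he", him, his]
    th: [ผม, ครับ, สามี]
  - label: female
    en: [mrs, ms, madam, wife, grandmother, "she", her, hers]
    th: [ดิฉัน, ค่ะ, ภรรยา]
source_cue:
  - label: self
    en: [i, me, my own, myself]
    th: [ผมเป็น, ฉันเป็น, ดิฉันเป็น, ตัวเอง, เราเป็น]
  - label: family_member
    en: [mother, father, mom, dad, grandmother, grandfather, sister, brother, aunt, uncle, son, daughter, wife, husband]
    th: [แม่, พ่อ, ยาย, ปู่, ย่า, ตา, พี่ชาย, น้องสาว, พี่สาว, น้องชาย, ลูก, สามี, ภรรยา]
  - label: acquaintance
    en: [friend, neighbor, neighbour, colleague, coworker]
    th: [เพื่อน, เพื่อนบ้าน, คนรู้จัก]
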