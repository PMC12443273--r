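# Curated Thai dictionary for longest-match word segmentation.
# One word per line; lines starting with '#' are ignored.
# Coverage: NCD vocabulary, pronouns, kin terms, particles, common verbs
# and nouns seen in health-related social media comments.
กลัว
กวน
ก็
กังวล
กิน
กินหวาน
กี่
ขนม
ของ
ขอบคุณ
ขา
ขึ้น
ข้าว
คน
ครับ
ครอบครัว
ความดัน
ความดันโลหิตสูง
คอ
คิด
คีโม
คุณ
คุมอาหาร
ค่ะ
ค่า
จริง
จะ
จาก
จ้า
ฉัน
ฉายแสง
ฉีด
ชา
ช่วง
ช่วย
ซื้อ
ดี
ดีขึ้น
ดิฉัน
ดื่ม
ดูแล
ด้วย
ตรวจ
ตอน
ตอนนี้
ตัวเอง
ตับ
ตา
ติด
ต้อง
ถาม
ถุงลมโป่งพอง
ทราบ
ทาน
ทำ
ทำไม
ทุก
ทุกวัน
ที่
ที่ไหน
นอน
นะ
นาน
นี้
น้อง
น้องสาว
น้ำ
น้ำตาล
น้ำตาลสูง
น้ำหนัก
บอก
บุหรี่
ปวด
ปวดหัว
ปี
ปู่
ผม
ผล
ผ่าตัด
พบ
พยาบาล
พ่อ
ฟอกไต
ภูมิใจ
มะเร็ง
มะเร็งปอด
มะเร็งเต้านม
มา
มาก
มั้ย
ยังไง
ยา
ยาย
รอ
รักษา
ระยะ
รู้
รู้สึก
ลด
ลอง
วัน
ว่า
สงสัย
สวัสดี
สอง
สาม
สามารถ
สุขภาพ
สูบ
สูบบุหรี่
สู้
หมอ
หรือ
หรือเปล่า
หลัง
หวาน
หอบ
หอบหืด
หัวใจ
หาย
หายช้า
อยาก
อยู่
อะไร
อาการ
อาหาร
อาหารหวาน
อินซูลิน
ออกกำลังกาย
อ่อนเพลีย
ฮะ
เจอ
เจ็บ
เจ็บหน้าอก
เบาหวาน
เป็น
เพราะ
เพื่อน
เมื่อย
เรา
เริ่ม
เลย
เล่า
เหนื่อย
เหนื่อยง่าย
เหล้า
เอง
แผล
แพทย์
แม่
แล้ว
โรค
โรคปอด
โรคหัวใจ
โรงพยาบาล
ใคร
ใจ
ให้
ไหม
ไอ
ไป
ได้
ไต
ไม่
และ
กับ
ใน
คือ
ๆ
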