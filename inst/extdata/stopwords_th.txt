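# Thai stopwords (particles, common function words), one per line.
ก็
จะ
จาก
ของ
ครับ
ค่ะ
จ้า
ด้วย
ที่
นะ
นี้
มา
มาก
แล้ว
ว่า
หรือ
อยู่
เป็น
เลย
ให้
ไป
ได้
ไม่
และ
กับ
ใน
คือ
ๆ
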