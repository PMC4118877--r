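{"id": "t01", "text": "damn flu, home with a fever watching TV.", "timestamp": "2012-01-09", "region": "MD"}
{"id": "t02", "text": "sore throat and a nasty cough, need some cough syrup", "timestamp": "2012-01-10", "region": "NY"}
{"id": "t03", "text": "got my flu shot today, arm hurts", "timestamp": "2012-01-11", "region": "MD"}
{"id": "t04", "text": "sneezing nonstop, itchy eyes... allergy meds aren't working", "timestamp": "2012-04-02", "region": "CA"}
{"id": "t05", "text": "runny nose again. spring allergies are the worst", "timestamp": "2012-04-03", "region": "CA"}
{"id": "t06", "text": "check out this great deal http://spam.example.com", "timestamp": "2012-04-03", "region": "NY"}
{"id": "t07", "text": "headache all day, going to bed early", "timestamp": "2012-04-04", "region": "TX"}
{"id": "t08", "text": "red eye after swimming, grabbed some eye drops", "timestamp": "2012-04-05", "region": "TX"}
{"id": "t09", "text": "doctor gave me antibiotics for the ear infection", "timestamp": "2012-04-06", "region": "NY"}
{"id": "t10", "text": "watching tv with the family tonight", "timestamp": "2012-04-07", "region": "MD"}
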