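name,ref_cost,ref_size,ref_index,target_size
bioreactor (m3),520000,100,567.3,295
seed fermenter (m3),120000,10,567.3,30
air compressor (kW),95000,250,567.3,400
media sterilizer (m3/h),140000,30,567.3,50
centrifuge (m3/h),330000,40,567.3,60
homogenizer (m3/h),180000,20,567.3,30
extraction tank (m3),75000,50,567.3,150
rotary dryer (kg/h),210000,500,567.3,700
storage tanks (m3),60000,100,567.3,300
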