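# First-order queen contiguity among the 31 mainland China province-level
# units, one neighbour pair per line. Includes a Hainan-Guangdong bridge so
# that no region is an island. One conventional choice; not authoritative.
Beijing,Tianjin
Beijing,Hebei
Tianjin,Hebei
Hebei,Shanxi
Hebei,Inner Mongolia
Hebei,Liaoning
Hebei,Shandong
Hebei,Henan
Shanxi,Inner Mongolia
Shanxi,Shaanxi
Shanxi,Henan
Inner Mongolia,Liaoning
Inner Mongolia,Jilin
Inner Mongolia,Heilongjiang
Inner Mongolia,Shaanxi
Inner Mongolia,Ningxia
Inner Mongolia,Gansu
Liaoning,Jilin
Jilin,Heilongjiang
Shanghai,Jiangsu
Shanghai,Zhejiang
Jiangsu,Zhejiang
Jiangsu,Anhui
Jiangsu,Shandong
Zhejiang,Anhui
Zhejiang,Jiangxi
Zhejiang,Fujian
Anhui,Jiangxi
Anhui,Henan
Anhui,Hubei
Anhui,Shandong
Fujian,Jiangxi
Fujian,Guangdong
Jiangxi,Hubei
Jiangxi,Hunan
Jiangxi,Guangdong
Shandong,Henan
Henan,Shaanxi
Henan,Hubei
Hubei,Shaanxi
Hubei,Chongqing
Hubei,Hunan
Hunan,Guangdong
Hunan,Guangxi
Hunan,Guizhou
Hunan,Chongqing
Guangdong,Guangxi
Guangdong,Hainan
Guangxi,Guizhou
Guangxi,Yunnan
Chongqing,Guizhou
Chongqing,Sichuan
Chongqing,Shaanxi
Sichuan,Guizhou
Sichuan,Yunnan
Sichuan,Tibet
Sichuan,Qinghai
Sichuan,Gansu
Sichuan,Shaanxi
Guizhou,Yunnan
Yunnan,Tibet
Tibet,Qinghai
Tibet,Xinjiang
Shaanxi,Ningxia
Shaanxi,Gansu
Gansu,Ningxia
Gansu,Qinghai
Gansu,Xinjiang
Qinghai,Xinjiang
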