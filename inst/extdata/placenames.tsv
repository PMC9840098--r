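prefecture	city	town
神奈川県	横浜市中区	本町
神奈川県	川崎市川崎区	駅前
東京都	世田谷区	桜丘
東京都	八王子市	元本郷町
大阪府	大阪市北区	梅田
大阪府	堺市堺区	南瓦町
山口県	宇部市	常盤町
愛知県	名古屋市中村区	名駅
北海道	札幌市中央区	大通西
福岡県	福岡市博多区	博多駅前
京都府	京都市左京区	吉田本町
兵庫県	神戸市中央区	三宮町
広島県	広島市中区	大手町
宮城県	仙台市青葉区	中央
新潟県	新潟市中央区	学校町
石川県	金沢市	広坂
岡山県	岡山市北区	表町
熊本県	熊本市中央区	水前寺
静岡県	静岡市葵区	追手町
長野県	長野市	大字鶴賀
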