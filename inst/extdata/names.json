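[
  {"name": "Amara Okafor", "sex": "female"},
  {"name": "Sofia Ramirez", "sex": "female"},
  {"name": "Mei-Ling Chen", "sex": "female"},
  {"name": "Priya Sharma", "sex": "female"},
  {"name": "Fatima Al-Sayed", "sex": "female"},
  {"name": "Keisha Williams", "sex": "female"},
  {"name": "Ingrid Johansson", "sex": "female"},
  {"name": "Yuki Tanaka", "sex": "female"},
  {"name": "Aaliyah Jackson", "sex": "female"},
  {"name": "Rosa Delgado", "sex": "female"},
  {"name": "Nadia Petrova", "sex": "female"},
  {"name": "Chioma Eze", "sex": "female"},
  {"name": "Leilani Kahale", "sex": "female"},
  {"name": "Hannah Goldberg", "sex": "female"},
  {"name": "Siobhan O'Connor", "sex": "female"},
  {"name": "Zainab Hussain", "sex": "female"},
  {"name": "Marisol Fuentes", "sex": "female"},
  {"name": "Astrid Nielsen", "sex": "female"},
  {"name": "Thandiwe Dlamini", "sex": "female"},
  {"name": "Emily Carter", "sex": "female"},
  {"name": "Lucia Moretti", "sex": "female"},
  {"name": "Anong Srisuwan", "sex": "female"},
  {"name": "Gabriela Santos", "sex": "female"},
  {"name": "Noor Rahman", "sex": "female"},
  {"name": "Katarzyna Nowak", "sex": "female"},
  {"name": "Imani Mwangi", "sex": "female"},
  {"name": "Soo-Jin Park", "sex": "female"},
  {"name": "Valentina Rossi", "sex": "female"},
  {"name": "Bridget Murphy", "sex": "female"},
  {"name": "Esperanza Villanueva", "sex": "female"},
  {"name": "Anya Volkov", "sex": "female"},
  {"name": "Dalia Haddad", "sex": "female"},
  {"name": "Margaret Whitfield", "sex": "female"},
  {"name": "Xiomara Pena", "sex": "female"},
  {"name": "Freya Andersen", "sex": "female"},
  {"name": "Tendai Moyo", "sex": "female"},
  {"name": "Sakura Yamamoto", "sex": "female"},
  {"name": "Olivia Bennett", "sex": "female"},
  {"name": "Anaya Patel", "sex": "female"},
  {"name": "Catalina Herrera", "sex": "female"},
  {"name": "Maryam Karimi", "sex": "female"},
  {"name": "Josephine Baptiste", "sex": "female"},
  {"name": "Linnea Virtanen", "sex": "female"},
  {"name": "Adaeze Nwosu", "sex": "female"},
  {"name": "Paloma Cruz", "sex": "female"},
  {"name": "Rachel Steinberg", "sex": "female"},
  {"name": "Kiri Waititi", "sex": "female"},
  {"name": "Elif Yilmaz", "sex": "female"},
  {"name": "Grace Thompson", "sex": "female"},
  {"name": "Huong Nguyen", "sex": "female"},
  {"name": "Kwame Mensah", "sex": "male"},
  {"name": "Diego Fernandez", "sex": "male"},
  {"name": "Wei Zhang", "sex": "male"},
  {"name": "Arjun Gupta", "sex": "male"},
  {"name": "Omar Khalil", "sex": "male"},
  {"name": "Marcus Johnson", "sex": "male"},
  {"name": "Lars Eriksson", "sex": "male"},
  {"name": "Hiroshi Sato", "sex": "male"},
  {"name": "Jamal Robinson", "sex": "male"},
  {"name": "Mateo Gutierrez", "sex": "male"},
  {"name": "Dmitri Sokolov", "sex": "male"},
  {"name": "Emeka Obi", "sex": "male"},
  {"name": "Kai Mahelona", "sex": "male"},
  {"name": "David Rosenthal", "sex": "male"},
  {"name": "Liam Gallagher", "sex": "male"},
  {"name": "Yusuf Demir", "sex": "male"},
  {"name": "Rafael Mendoza", "sex": "male"},
  {"name": "Henrik Larsen", "sex": "male"},
  {"name": "Sipho Ndlovu", "sex": "male"},
  {"name": "James Whitmore", "sex": "male"},
  {"name": "Giovanni Ricci", "sex": "male"},
  {"name": "Somchai Charoen", "sex": "male"},
  {"name": "Thiago Oliveira", "sex": "male"},
  {"name": "Hassan Farah", "sex": "male"},
  {"name": "Piotr Kowalski", "sex": "male"},
  {"name": "Baraka Otieno", "sex": "male"},
  {"name": "Min-Jun Kim", "sex": "male"},
  {"name": "Alessandro Conti", "sex": "male"},
  {"name": "Declan Byrne", "sex": "male"},
  {"name": "Santiago Reyes", "sex": "male"},
  {"name": "Nikolai Ivanov", "sex": "male"},
  {"name": "Tariq Nasser", "sex": "male"},
  {"name": "Edward Pemberton", "sex": "male"},
  {"name": "Joaquin Salazar", "sex": "male"},
  {"name": "Magnus Holm", "sex": "male"},
  {"name": "Tawanda Chikwanda", "sex": "male"},
  {"name": "Kenji Nakamura", "sex": "male"},
  {"name": "William Hayes", "sex": "male"},
  {"name": "Rohan Mehta", "sex": "male"},
  {"name": "Andres Vargas", "sex": "male"},
  {"name": "Farid Rezaei", "sex": "male"},
  {"name": "Antoine Toussaint", "sex": "male"},
  {"name": "Eero Makinen", "sex": "male"},
  {"name": "Chinedu Okeke", "sex": "male"},
  {"name": "Esteban Morales", "sex": "male"},
  {"name": "Samuel Abramson", "sex": "male"},
  {"name": "Nikau Parata", "sex": "male"},
  {"name": "Mehmet Kaya", "sex": "male"},
  {"name": "Thomas Sinclair", "sex": "male"},
  {"name": "Duc Tran", "sex": "male"}
]
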